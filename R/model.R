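# FH-R model: vector field, Jacobian, canonical parameter sets.
#
# d^a v / dt^a = v - v^3/3 - w + y + I
# d^a w / dt^a = delta (a + v - b w)
# d^a y / dt^a = mu (c - v - d y)
#
# v is on a mV-like scale, t on a ms-like scale; all constants are treated as
# plain dimensionless reals.

# Base constants shared by the five canonical sets; per-set overrides below.
.fhr_base <- list(a = 0.7, b = 0.8, c = -0.775, d = 1, delta = 0.08,
                  mu = 1e-4, I = 0.3125)

.fhr_overrides <- list(
  I   = list(),
  II  = list(I = 0.4),
  III = list(mu = 0.18, I = 3),
  IV  = list(c = 1.3),
  V   = list(c = -0.908, mu = 0.002)
)

#' Construct an FH-R parameter set
#'
#' Bundles the seven model constants. `b`, `d`, `delta` and `mu` must be
#' strictly positive. Condition (A), `b*d < b + d`, guarantees a unique
#' equilibrium and underpins the whole analytic stability machinery; it holds
#' for every bundled preset. A user-supplied set violating (A) is accepted
#' for simulation but triggers a warning, and the analysis functions refuse
#' it.
#'
#' @param a,b,c,d,delta,mu,I model constants (defaults are the base values
#'   shared by the canonical presets).
#' @param label optional preset name attached for bookkeeping.
#' @return An object of class `fhr_params` (a named list).
#' @seealso [fhr_preset()] for the canonical sets I-V.
#' @export
#' @examples
#' p <- fhr_params(I = 0.5)
#' fhr_rhs(c(0, 0, 0), p)
fhr_params <- function(a = 0.7, b = 0.8, c = -0.775, d = 1, delta = 0.08,
                       mu = 1e-4, I = 0.3125, label = NULL) {
  vals <- list(a = a, b = b, c = c, d = d, delta = delta, mu = mu, I = I)
  for (nm in names(vals)) {
    x <- vals[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("parameter '%s' must be a single finite number", nm),
           call. = FALSE)
  }
  if (b <= 0 || d <= 0 || delta <= 0 || mu <= 0)
    stop("b, d, delta and mu must be strictly positive", call. = FALSE)
  obj <- structure(vals, label = label, class = "fhr_params")
  if (!assumption_a(obj))
    warning("condition (A) b*d < b + d does not hold; the equilibrium need ",
            "not be unique and the stability analysis will refuse this set",
            call. = FALSE)
  obj
}

#' Canonical FH-R parameter sets
#'
#' Returns one of the five canonical parameter sets. All share
#' a = 0.7, b = 0.8, d = 1, delta = 0.08, c = -0.775, mu = 1e-4 with the
#' per-set overrides: I: I = 0.3125; II: I = 0.4; III: mu = 0.18, I = 3;
#' IV: c = 1.3; V: c = -0.908, mu = 0.002.
#'
#' @param label one of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @return An `fhr_params` object.
#' @export
#' @examples
#' fhr_preset("I")
fhr_preset <- function(label) {
  label <- as.character(label)[1]
  if (!label %in% names(.fhr_overrides))
    stop("unknown preset '", label, "'; valid presets: ",
         paste(names(.fhr_overrides), collapse = ", "), call. = FALSE)
  vals <- modifyList(.fhr_base, .fhr_overrides[[label]])
  do.call(fhr_params, c(vals, list(label = label)))
}

#' Check condition (A)
#'
#' Condition (A) is `b*d < b + d`. Under (A) the characteristic cubic of the
#' equilibrium equation is strictly increasing, so the model has exactly one
#' equilibrium for every applied current I.
#'
#' @param params an `fhr_params` object.
#' @return `TRUE` or `FALSE`.
#' @export
assumption_a <- function(params) {
  params$b * params$d < params$b + params$d
}

#' FH-R right-hand side
#'
#' Evaluates the vector field at a state `(v, w, y)`.
#'
#' @param state numeric vector `c(v, w, y)`.
#' @param params an `fhr_params` object.
#' @return Numeric vector `c(f1, f2, f3)` of derivatives.
#' @export
#' @examples
#' fhr_rhs(c(0, 0, 0), fhr_preset("I"))
fhr_rhs <- function(state, params) {
  stopifnot(is.numeric(state), length(state) == 3L)
  v <- state[1]; w <- state[2]; y <- state[3]
  c(v - v^3 / 3 - w + y + params$I,
    params$delta * (params$a + v - params$b * w),
    params$mu * (params$c - v - params$d * y))
}

# Closure form of the field used by the integrator (avoids list lookups in
# the per-step callback).
fhr_field <- function(params) {
  a <- params$a; b <- params$b; cc <- params$c; d <- params$d
  delta <- params$delta; mu <- params$mu; I <- params$I
  function(x) {
    v <- x[1]; w <- x[2]; y <- x[3]
    c(v - v^3 / 3 - w + y + I,
      delta * (a + v - b * w),
      mu * (cc - v - d * y))
  }
}

#' Jacobian of the FH-R model at a voltage
#'
#' The Jacobian at a fixed point depends on the state only through `v*`:
#' rows `[[1 - v*^2, -1, 1], [delta, -delta*b, 0], [-mu, 0, -mu*d]]`.
#'
#' @param v_star voltage at which to evaluate.
#' @param params an `fhr_params` object.
#' @return A 3 x 3 numeric matrix.
#' @export
fhr_jacobian <- function(v_star, params) {
  matrix(c(1 - v_star^2, -1,                   1,
           params$delta, -params$delta * params$b, 0,
           -params$mu,   0,                    -params$mu * params$d),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("v", "w", "y"), c("v", "w", "y")))
}

#' @export
print.fhr_params <- function(x, ...) {
  lab <- attr(x, "label")
  cat("FH-R parameter set", if (!is.null(lab)) paste0("(preset ", lab, ")"),
      "\n")
  cat(sprintf("  a=%g  b=%g  c=%g  d=%g  delta=%g  mu=%g  I=%g\n",
              x$a, x$b, x$c, x$d, x$delta, x$mu, x$I))
  cat("  condition (A) b*d < b+d:", if (assumption_a(x)) "holds" else
      "VIOLATED", "\n")
  invisible(x)
}

#' Read / write a parameter set as a flat key-value config
#'
#' The on-disk format is a flat YAML mapping with keys
#' `a, b, c, d, delta, mu, I` (and optionally `label`), as consumed by the
#' command-line interface.
#'
#' @param params an `fhr_params` object.
#' @param path file path.
#' @return `write_params_config` returns `path` invisibly;
#'   `read_params_config` returns an `fhr_params` object.
#' @export
write_params_config <- function(params, path) {
  lst <- unclass(params)
  attr(lst, "label") <- NULL
  if (!is.null(attr(params, "label"))) lst$label <- attr(params, "label")
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  lst <- yaml::read_yaml(path)
  keys <- c("a", "b", "c", "d", "delta", "mu", "I")
  missing <- setdiff(keys, names(lst))
  if (length(missing))
    stop("config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  do.call(fhr_params, lst[c(keys, intersect("label", names(lst)))])
}
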