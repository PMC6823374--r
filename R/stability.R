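# Analytic machinery: equilibrium, spectrum, fractional stability threshold,
# chaos condition, classical and fractional Hopf structure.
#
# Equilibria satisfy w* = (v* + a)/b, y* = (c - v*)/d and the cubic
# F(v*) = v*^3 - 3 p v* = q with p = 1 - 1/b - 1/d, q = 3I - 3a/b + 3c/d.
# Under condition (A) (b*d < b + d) p < 0, F is strictly increasing and the
# equilibrium is unique for every q.

.require_A <- function(params) {
  if (!assumption_a(params))
    stop("condition (A) b*d < b + d is violated; the equilibrium analysis ",
         "does not apply to this parameter set", call. = FALSE)
}

#' Cubic invariants of the equilibrium equation
#'
#' Returns `p = 1 - 1/b - 1/d` and `q = 3I - 3a/b + 3c/d`, the coefficients
#' of the equilibrium cubic `F(v) = v^3 - 3 p v = q`.
#'
#' @param params an `fhr_params` object satisfying condition (A).
#' @return List with elements `p` and `q`.
#' @export
cubic_form <- function(params) {
  .require_A(params)
  list(p = 1 - 1 / params$b - 1 / params$d,
       q = 3 * params$I - 3 * params$a / params$b + 3 * params$c / params$d)
}

#' Equilibrium cubic F
#'
#' Evaluates `F(v) = v^3 - 3 p v` for the cubic invariant p of `params`.
#'
#' @param v voltage value(s).
#' @param params an `fhr_params` object satisfying condition (A).
#' @return `F(v)`, vectorized over `v`.
#' @export
cubic_F <- function(v, params) {
  p <- cubic_form(params)$p
  v^3 - 3 * p * v
}

# Map between applied current and the cubic right-hand side q.
.I_of_q <- function(q, params) q / 3 + params$a / params$b -
  params$c / params$d

#' Unique equilibrium of the FH-R model
#'
#' Solves `v^3 - 3 p v = q` for its unique real root (guaranteed by
#' condition (A)) via the companion-matrix eigenvalue route, then
#' back-substitutes `w* = (v* + a)/b`, `y* = (c - v*)/d`.
#'
#' @param params an `fhr_params` object satisfying condition (A).
#' @return Object of class `fhr_equilibrium`: list with `v_star`, `w_star`,
#'   `y_star`, `p`, `q`.
#' @export
#' @examples
#' fhr_equilibrium(fhr_preset("I"))
fhr_equilibrium <- function(params) {
  cf <- cubic_form(params)
  # monic cubic v^3 + 0 v^2 + (-3p) v + (-q) = 0; companion matrix route
  comp <- matrix(c(0, 0, cf$q,
                   1, 0, 3 * cf$p,
                   0, 1, 0), nrow = 3, byrow = TRUE)
  ev <- eigen(comp, only.values = TRUE)$values
  ev <- as.complex(ev)
  v_star <- Re(ev[which.min(abs(Im(ev)))])
  structure(list(v_star = v_star,
                 w_star = (v_star + params$a) / params$b,
                 y_star = (params$c - v_star) / params$d,
                 p = cf$p, q = cf$q, params = params),
            class = "fhr_equilibrium")
}

#' @export
print.fhr_equilibrium <- function(x, ...) {
  cat(sprintf("FH-R equilibrium: v*=%.6f w*=%.6f y*=%.6f  (p=%g, q=%g)\n",
              x$v_star, x$w_star, x$y_star, x$p, x$q))
  invisible(x)
}

#' Eigenvalue spectrum at the equilibrium
#'
#' Computes the three eigenvalues of the Jacobian at the unique equilibrium
#' by two independent routes -- the roots of the characteristic cubic
#' `Q(lambda)` with its closed-form coefficients, and a direct numerical
#' eigendecomposition of the Jacobian -- and verifies that they agree to
#' 1e-8. The sign of the discriminant of Q decides the structure: negative
#' means one real root plus a complex-conjugate pair, positive means three
#' distinct real roots.
#'
#' @param params an `fhr_params` object satisfying condition (A).
#' @return Object of class `fhr_spectrum`: list with `values` (complex,
#'   length 3), `lambda1` (smallest real eigenvalue), `pair` (the complex
#'   pair, or `NULL` when the spectrum is all-real), `det_J`, `trace_J`,
#'   `discriminant`, `has_pair`, `equilibrium`.
#' @export
#' @examples
#' eigen_spectrum(fhr_preset("I"))
eigen_spectrum <- function(params) {
  eq <- fhr_equilibrium(params)
  v <- eq$v_star
  b <- params$b; d <- params$d; delta <- params$delta; mu <- params$mu
  tr <- 1 - v^2 - delta * b - mu * d
  M <- delta - delta * b + mu - d * mu + b * d * delta * mu +
    b * delta * v^2 + d * mu * v^2
  detJ <- mu * delta * ((b * d - b - d) - b * d * v^2)
  # route 1: roots of Q(lambda) = lambda^3 - tr lambda^2 + M lambda - det
  roots <- polyroot(c(-detJ, M, -tr, 1))
  # route 2: direct Jacobian eigendecomposition (mutual oracle)
  evJ <- as.complex(eigen(fhr_jacobian(v, params), only.values = TRUE)$values)
  # nearest-neighbour set distance (robust when eigenvalue real parts cross)
  setdist <- max(vapply(roots, function(z) min(Mod(z - evJ)), numeric(1)),
                 vapply(evJ, function(z) min(Mod(z - roots)), numeric(1)))
  if (setdist > 1e-8)
    stop("internal inconsistency: characteristic-polynomial roots and ",
         "Jacobian eigenvalues disagree beyond 1e-8", call. = FALSE)
  # discriminant of lambda^3 + A lambda^2 + B lambda + C
  A <- -tr; B <- M; C <- -detJ
  disc <- 18 * A * B * C - 4 * A^3 * C + A^2 * B^2 - 4 * B^3 - 27 * C^2
  vals <- roots[order(Re(roots), Im(roots))]
  if (disc < 0) {
    i_real <- which.min(abs(Im(vals)))
    lambda1 <- Re(vals[i_real])
    pair <- vals[-i_real]
  } else {
    lambda1 <- min(Re(vals))
    pair <- NULL
    vals <- complex(real = sort(Re(vals)), imaginary = 0)
  }
  structure(list(values = vals, lambda1 = lambda1, pair = pair,
                 det_J = detJ, trace_J = tr, discriminant = disc,
                 has_pair = !is.null(pair), equilibrium = eq,
                 params = params),
            class = "fhr_spectrum")
}

#' @export
print.fhr_spectrum <- function(x, ...) {
  cat("Eigenvalues at the FH-R equilibrium:\n")
  for (z in x$values)
    cat(sprintf("  %.8g %+.8gi\n", Re(z), Im(z)))
  cat(sprintf("  trace=%.6g det=%.6g discriminant %s 0\n", x$trace_J,
              x$det_J, if (x$discriminant < 0) "<" else ">"))
  invisible(x)
}

#' Critical fractional exponent for asymptotic stability
#'
#' When the spectrum has a complex-conjugate pair, the equilibrium of the
#' fractional system of order alpha is asymptotically stable iff
#' `alpha < alpha*` with `alpha* = (2/pi) |arg(lambda_pair)|`. The
#' equivalent closed form
#' `(2/pi) arccos((trace - lambda1) sqrt(-lambda1) / (2 sqrt(-det)))`
#' is evaluated as an internal cross-check (agreement to 1e-6 enforced).
#' A value above 1 means the equilibrium is stable for every admissible
#' alpha. All-real spectra have no fractional Hopf threshold: `NA` is
#' returned (negative real eigenvalues are stable for every alpha <= 1).
#'
#' @param params an `fhr_params` object satisfying condition (A).
#' @param spectrum optional precomputed [eigen_spectrum()] result.
#' @return `alpha*` as a number, or `NA_real_` when the spectrum is
#'   all-real.
#' @export
#' @examples
#' critical_alpha(fhr_preset("I"))  # ~0.80828
critical_alpha <- function(params, spectrum = NULL) {
  sp <- if (is.null(spectrum)) eigen_spectrum(params) else spectrum
  if (!sp$has_pair) return(NA_real_)
  a_arg <- (2 / pi) * abs(Arg(sp$pair[1]))
  # closed form in terms of lambda1, trace and det (lambda1 < 0 and
  # det < 0 are guaranteed under condition (A) when a pair exists)
  ratio <- (sp$trace_J - sp$lambda1) * sqrt(-sp$lambda1) /
    (2 * sqrt(-sp$det_J))
  a_acos <- (2 / pi) * acos(min(1, max(-1, ratio)))
  if (abs(a_acos - a_arg) > 1e-6)
    stop("internal inconsistency: the arccos and argument forms of the ",
         "critical exponent disagree beyond 1e-6", call. = FALSE)
  a_arg
}

#' Necessary chaos threshold
#'
#' For a saddle-focus of index 2 (one negative real eigenvalue plus a
#' complex pair with positive real part), the fractional system can exhibit
#' chaos only for `alpha > (2/pi) atan(|Im lambda| / Re lambda)`. This is a
#' necessary condition, not sufficient. Returns `NA` when the equilibrium
#' is not a saddle-focus of index 2.
#'
#' @inheritParams critical_alpha
#' @return The threshold, or `NA_real_`.
#' @export
chaos_alpha <- function(params, spectrum = NULL) {
  sp <- if (is.null(spectrum)) eigen_spectrum(params) else spectrum
  if (!sp$has_pair || Re(sp$pair[1]) <= 0 || sp$lambda1 >= 0)
    return(NA_real_)
  (2 / pi) * atan(abs(Im(sp$pair[1])) / Re(sp$pair[1]))
}

#' Saddle-focus of index 2?
#'
#' One negative real eigenvalue plus a complex-conjugate pair with positive
#' real part.
#'
#' @inheritParams critical_alpha
#' @return `TRUE`/`FALSE`.
#' @export
is_saddle_focus_index2 <- function(params, spectrum = NULL) {
  sp <- if (is.null(spectrum)) eigen_spectrum(params) else spectrum
  sp$has_pair && Re(sp$pair[1]) > 0 && sp$lambda1 < 0
}

#' Alpha-independent stability window
#'
#' The trace of the Jacobian vanishes at `v = gamma1 = -sqrt(1 - delta*b -
#' mu*d)` and `gamma2 = +sqrt(...)`. For `q <= F(gamma1)` or
#' `q >= F(gamma2)` the equilibrium is asymptotically stable for every
#' fractional exponent; mapped to the applied current this gives the window
#' `(I_low, I_high)` inside which stability can depend on alpha.
#'
#' @param params an `fhr_params` object satisfying condition (A).
#' @return List with `gamma1`, `gamma2`, `F_gamma1`, `F_gamma2`, `I_low`,
#'   `I_high` and `independent` (`TRUE` when the set's own current lies
#'   outside the open window, so its stability is alpha-independent). When
#'   `1 - delta*b - mu*d <= 0` there are no trace-zero voltages: the gammas
#'   are `NA` and `independent` reports whether all eigenvalues have
#'   negative real part.
#' @export
#' @examples
#' alpha_independent_stability(fhr_preset("I"))
alpha_independent_stability <- function(params) {
  cf <- cubic_form(params)
  s <- 1 - params$delta * params$b - params$mu * params$d
  if (s <= 0) {
    sp <- eigen_spectrum(params)
    return(list(gamma1 = NA_real_, gamma2 = NA_real_,
                F_gamma1 = NA_real_, F_gamma2 = NA_real_,
                I_low = NA_real_, I_high = NA_real_,
                independent = all(Re(sp$values) < 0)))
  }
  g2 <- sqrt(s)
  Fg1 <- (-g2)^3 - 3 * cf$p * (-g2)
  Fg2 <- g2^3 - 3 * cf$p * g2
  list(gamma1 = -g2, gamma2 = g2, F_gamma1 = Fg1, F_gamma2 = Fg2,
       I_low = .I_of_q(Fg1, params), I_high = .I_of_q(Fg2, params),
       independent = cf$q <= Fg1 || cf$q >= Fg2)
}

#' Classical Hopf bifurcation currents
#'
#' Locates the two super-critical Hopf points of the classical-order
#' (alpha = 1) model in the applied current I. Two methods are kept
#' deliberately distinct:
#' \describe{
#'   \item{`trace_zero`}{inverts the equilibrium cubic at the trace-zero
#'     voltages gamma1, gamma2 and maps q back to I (the closed-form
#'     approximation; it ignores the real eigenvalue's contribution).}
#'   \item{`continuation`}{root-finds the true crossing
#'     `Re(lambda_pair)(I) = 0` by bisection (tolerance 1e-8 in I) in a
#'     window of half-width 0.05 around each trace-zero estimate.}
#' }
#' The small discrepancy between the two (about 3e-4 in I) is the trace-zero
#' approximation error, not a numerical artifact.
#'
#' @param params an `fhr_params` object satisfying condition (A); its own
#'   `I` is ignored.
#' @param method `"continuation"` (default) or `"trace_zero"`.
#' @param tol bisection tolerance in I.
#' @return Named numeric vector `c(HB1, HB2)` (either may be `NA` if no
#'   bracketing sign change is found), with the method in attribute
#'   `"method"`.
#' @export
#' @examples
#' classical_hopf_currents(fhr_preset("I"))
classical_hopf_currents <- function(params,
                                    method = c("continuation", "trace_zero"),
                                    tol = 1e-8) {
  method <- match.arg(method)
  ais <- alpha_independent_stability(params)
  if (!is.finite(ais$I_low))
    stop("no trace-zero voltages: 1 - delta*b - mu*d <= 0", call. = FALSE)
  if (method == "trace_zero") {
    out <- c(HB1 = ais$I_low, HB2 = ais$I_high)
  } else {
    re_pair <- function(I) {
      p2 <- params; p2$I <- I
      sp <- eigen_spectrum(p2)
      if (!sp$has_pair) NA_real_ else Re(sp$pair[1])
    }
    locate <- function(lo, hi) {
      flo <- re_pair(lo); fhi <- re_pair(hi)
      if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
        return(NA_real_)
      uniroot(re_pair, c(lo, hi), tol = tol)$root
    }
    out <- c(HB1 = locate(ais$I_low - 0.05, ais$I_low + 0.05),
             HB2 = locate(ais$I_high - 0.05, ais$I_high + 0.05))
  }
  attr(out, "method") <- method
  out
}

#' Stability index of a fractional eigenvalue
#'
#' `n_i(alpha, lambda) = alpha*pi/2 - |arg(lambda)|` plays the role the real
#' part plays in classical systems: negative means the mode is stable at
#' exponent alpha, positive unstable.
#'
#' @param alpha fractional exponent.
#' @param lambda eigenvalue (complex or real), vectorized.
#' @return Numeric.
#' @export
n_index <- function(alpha, lambda) {
  alpha * pi / 2 - abs(Arg(as.complex(lambda)))
}

#' Fractional Hopf bifurcation curve over a current grid
#'
#' For each current in `I_grid`, recomputes the equilibrium and spectrum and
#' reports the critical exponent `alpha*`; grid points where the
#' discriminant of the characteristic cubic is positive (all-real spectrum,
#' no fractional Hopf) are masked with `NA`.
#'
#' @param params an `fhr_params` object (its own `I` is ignored).
#' @param I_grid numeric vector of applied currents, normally inside the
#'   `(I_low, I_high)` window of [alpha_independent_stability()].
#' @return `data.frame` with columns `I`, `alpha_star`, `masked`.
#' @export
hopf_curve <- function(params, I_grid) {
  stopifnot(length(I_grid) >= 1)
  res <- vapply(I_grid, function(I) {
    p2 <- params; p2$I <- I
    sp <- eigen_spectrum(p2)
    if (sp$discriminant > 0) c(NA_real_, 1) else
      c(critical_alpha(p2, sp), 0)
  }, numeric(2))
  data.frame(I = I_grid, alpha_star = res[1, ], masked = res[2, ] == 1)
}

#' Full stability report
#'
#' Bundles the equilibrium, spectrum, alpha-independent window, critical
#' exponent, chaos threshold and both Hopf-current variants into one list,
#' as emitted by the `analyze` CLI subcommand.
#'
#' @param params an `fhr_params` object satisfying condition (A).
#' @return Object of class `fhr_stability_report` (a named list).
#' @export
#' @examples
#' stability_report(fhr_preset("I"))
stability_report <- function(params) {
  sp <- eigen_spectrum(params)
  eq <- sp$equilibrium
  ais <- alpha_independent_stability(params)
  hopf_cont <- tryCatch(classical_hopf_currents(params, "continuation"),
                        error = function(e) c(HB1 = NA_real_,
                                              HB2 = NA_real_))
  structure(list(
    label = attr(params, "label"),
    params = unclass(params),
    assumption_A = assumption_a(params),
    equilibrium = c(v = eq$v_star, w = eq$w_star, y = eq$y_star),
    p = eq$p, q = eq$q,
    eigenvalues = sp$values,
    lambda1 = sp$lambda1,
    trace_J = sp$trace_J, det_J = sp$det_J,
    discriminant = sp$discriminant,
    saddle_focus_index2 = is_saddle_focus_index2(params, sp),
    gamma1 = ais$gamma1, gamma2 = ais$gamma2,
    F_gamma1 = ais$F_gamma1, F_gamma2 = ais$F_gamma2,
    I_low = ais$I_low, I_high = ais$I_high,
    alpha_independent = ais$independent,
    critical_alpha = critical_alpha(params, sp),
    chaos_alpha = chaos_alpha(params, sp),
    hopf_trace_zero = c(classical_hopf_currents(params, "trace_zero")),
    hopf_continuation = c(hopf_cont)
  ), class = "fhr_stability_report")
}

#' @export
print.fhr_stability_report <- function(x, ...) {
  cat("FH-R stability report",
      if (!is.null(x$label)) paste0("(preset ", x$label, ")"), "\n")
  cat(sprintf("  equilibrium: v*=%.6f w*=%.6f y*=%.6f\n",
              x$equilibrium["v"], x$equilibrium["w"], x$equilibrium["y"]))
  cat("  eigenvalues:",
      paste(sprintf("%.6g%+.6gi", Re(x$eigenvalues), Im(x$eigenvalues)),
            collapse = ", "), "\n")
  cat(sprintf("  alpha-independent window: I in (%.4f, %.4f)%s\n",
              x$I_low, x$I_high,
              if (x$alpha_independent) " [outside: alpha-independent]" else ""))
  cat(sprintf("  critical alpha*: %s   chaos threshold: %s\n",
              format(x$critical_alpha), format(x$chaos_alpha)))
  cat(sprintf("  Hopf currents: trace-zero (%.6f, %.6f); continuation (%s, %s)\n",
              x$hopf_trace_zero[1], x$hopf_trace_zero[2],
              format(x$hopf_continuation[1]),
              format(x$hopf_continuation[2])))
  invisible(x)
}
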