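# Two electrically (bidirectionally) coupled FH-R neurons and the
# similarity-function synchronization diagnostic.

# Stacked 6-dimensional field; the coupling g_e (v_j - v_i) enters only the
# voltage equations, symmetrically. The term is added even at g_e = 0 so a
# decoupled pair reproduces two single-neuron runs bit-for-bit.
coupled_field <- function(params, g_e) {
  a <- params$a; b <- params$b; cc <- params$c; d <- params$d
  delta <- params$delta; mu <- params$mu; I <- params$I
  function(x) {
    v1 <- x[1]; w1 <- x[2]; y1 <- x[3]
    v2 <- x[4]; w2 <- x[5]; y2 <- x[6]
    c(v1 - v1^3 / 3 - w1 + y1 + I + g_e * (v2 - v1),
      delta * (a + v1 - b * w1),
      mu * (cc - v1 - d * y1),
      v2 - v2^3 / 3 - w2 + y2 + I + g_e * (v1 - v2),
      delta * (a + v2 - b * w2),
      mu * (cc - v2 - d * y2))
  }
}

#' Simulate two electrically coupled FH-R neurons
#'
#' Integrates the stacked six-dimensional system under the same Caputo L1
#' scheme as the single neuron. Both neurons share one parameter set; the
#' coupling `g_e * (v_j - v_i)` acts on the voltage equations only and is
#' symmetric, so identical initial states stay identical for all time (the
#' synchronization manifold is exactly invariant under the update rule).
#'
#' @param params an `fhr_params` object (shared by both neurons).
#' @param g_e electrical coupling strength, non-negative.
#' @param alpha fractional exponent in (0, 1].
#' @param dt time step (ms).
#' @param t_end horizon in ms; ignored when `n_steps` given.
#' @param n_steps number of steps.
#' @param seeds integer pair; each neuron's initial state is an independent
#'   seeded perturbation of the equilibrium (see [perturbed_init()]).
#' @param init optional explicit initial state `c(v1,w1,y1,v2,w2,y2)`
#'   (overrides `seeds`).
#' @param perturbation_scale scale of the uniform initial perturbations.
#' @param guard,engine passed to [caputo_integrate()].
#' @return Object of class `fhr_coupled_trajectory` with `times`, `states`
#'   (columns v1,w1,y1,v2,w2,y2) and the configuration.
#' @export
#' @examples
#' ct <- coupled_simulate(fhr_preset("I"), g_e = 0.5, alpha = 1,
#'                        t_end = 20, seeds = c(1, 2))
coupled_simulate <- function(params, g_e, alpha, dt = 0.1, t_end = 2000,
                             n_steps = NULL, seeds = NULL, init = NULL,
                             perturbation_scale = 1, guard = 1e3,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "fhr_params"), g_e >= 0)
  if (is.null(n_steps)) n_steps <- round(t_end / dt)
  if (is.null(init)) {
    if (is.null(seeds) || length(seeds) != 2L)
      stop("two seeds (one per neuron) are required when no explicit ",
           "initial state is given", call. = FALSE)
    init <- c(perturbed_init(params, seeds[1], perturbation_scale),
              perturbed_init(params, seeds[2], perturbation_scale))
  } else {
    stopifnot(length(init) == 6L)
    if (is.null(seeds)) seeds <- c(NA_integer_, NA_integer_)
  }
  res <- caputo_integrate(coupled_field(params, g_e), init, alpha, dt,
                          n_steps, guard = guard, engine = engine)
  colnames(res$states) <- c("v1", "w1", "y1", "v2", "w2", "y2")
  structure(list(times = res$times, states = res$states, params = params,
                 g_e = g_e, alpha = alpha, dt = dt,
                 n_steps = as.integer(n_steps),
                 seeds = as.integer(seeds),
                 perturbation_scale = perturbation_scale, init = init,
                 engine = engine),
            class = "fhr_coupled_trajectory")
}

#' @export
print.fhr_coupled_trajectory <- function(x, ...) {
  cat(sprintf(
    "Coupled FH-R trajectory: g_e=%g alpha=%g dt=%g steps=%d seeds=(%s, %s)\n",
    x$g_e, x$alpha, x$dt, x$n_steps, format(x$seeds[1]), format(x$seeds[2])))
  invisible(x)
}

#' @export
as.data.frame.fhr_coupled_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states)
}

#' Similarity function between two voltage signals
#'
#' `S(lag)^2 = <(v1(t) - v2(t - lag))^2> / sqrt(<v1^2> <v2^2>)`, with the
#' time averages taken over the overlap window of the two (already
#' transient-free) series. `S(0) = 0` means complete synchronization;
#' anti-phase identical signals give `S(0) = 2`.
#'
#' @param v1,v2 numeric series of equal length.
#' @param lag non-negative integer lag, in steps.
#' @return `S(lag)` (non-negative), or `NA` with a warning when a series is
#'   identically zero (the normalization is undefined).
#' @export
#' @examples
#' x <- sin(seq(0, 10, 0.1))
#' similarity(x, x)        # 0
#' similarity(x, -x)       # 2
similarity <- function(v1, v2, lag = 0) {
  stopifnot(length(v1) == length(v2), lag >= 0, lag == round(lag),
            lag < length(v1))
  n <- length(v1)
  i1 <- (lag + 1):n
  i2 <- 1:(n - lag)
  den <- sqrt(mean(v1[i1]^2) * mean(v2[i2]^2))
  if (den == 0) {
    warning("similarity undefined: a signal is identically zero over the ",
            "window", call. = FALSE)
    return(NA_real_)
  }
  sqrt(mean((v1[i1] - v2[i2])^2) / den)
}

#' Similarity of a coupled trajectory after transient removal
#'
#' Discards the first `transient_fraction` of the samples and evaluates
#' [similarity()] on the voltage pair.
#'
#' @param ctraj an `fhr_coupled_trajectory`.
#' @param lag non-negative integer lag in steps.
#' @param transient_fraction fraction of initial samples discarded
#'   (default 0.5).
#' @return `S(lag)`.
#' @export
sync_similarity <- function(ctraj, lag = 0, transient_fraction = 0.5) {
  stopifnot(inherits(ctraj, "fhr_coupled_trajectory"),
            transient_fraction > 0, transient_fraction < 1)
  n <- nrow(ctraj$states)
  keep <- (floor(n * transient_fraction) + 1):n
  similarity(ctraj$states[keep, "v1"], ctraj$states[keep, "v2"], lag = lag)
}

#' Similarity sweep over coupling strengths
#'
#' Runs one independently seeded coupled simulation per coupling strength
#' and records `S(0)`; complete synchronization (CS) is declared where
#' `S(0) < cs_tolerance`. A divergent run is recorded (`diverged = TRUE`,
#' `S0 = NA`) rather than aborting the sweep.
#'
#' @param params an `fhr_params` object.
#' @param alpha fractional exponent.
#' @param g_e_grid coupling strengths to scan (default 25 points on
#'   \[0, 0.6\]).
#' @param dt,t_end solver configuration per run.
#' @param seeds base integer pair; run i uses `seeds + i`.
#' @param transient_fraction fraction discarded before averaging.
#' @param cs_tolerance CS threshold on S(0) (default 0.01).
#' @param perturbation_scale scale of the initial perturbations.
#' @param engine passed to [caputo_integrate()].
#' @param ... further arguments (e.g. `guard`) passed to
#'   [coupled_simulate()].
#' @return `data.frame` with columns `g_e`, `S0`, `cs`, `diverged`.
#' @export
sync_sweep <- function(params, alpha, g_e_grid = seq(0, 0.6, length.out = 25),
                       dt = 0.1, t_end = 2000, seeds = c(101, 202),
                       transient_fraction = 0.5, cs_tolerance = 0.01,
                       perturbation_scale = 1, engine = c("cpp", "r"), ...) {
  engine <- match.arg(engine)
  stopifnot(length(g_e_grid) >= 1)
  S0 <- numeric(length(g_e_grid))
  div <- logical(length(g_e_grid))
  for (i in seq_along(g_e_grid)) {
    S0[i] <- tryCatch({
      ct <- coupled_simulate(params, g_e = g_e_grid[i], alpha = alpha,
                             dt = dt, t_end = t_end, seeds = seeds + i,
                             perturbation_scale = perturbation_scale,
                             engine = engine, ...)
      sync_similarity(ct, lag = 0, transient_fraction = transient_fraction)
    }, fhr_divergence = function(e) {
      div[i] <<- TRUE
      NA_real_
    })
  }
  data.frame(g_e = g_e_grid, S0 = S0, cs = !is.na(S0) & S0 < cs_tolerance,
             diverged = div)
}
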