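# Shared helpers: hand-built trajectory objects and random parameter sets.

# Wrap a bare voltage series (plus resting w, y) as an fhr_trajectory so the
# spike/regime tools can be exercised on fully controlled synthetic traces.
fake_trajectory <- function(times, v, w = NULL, y = NULL,
                            params = fhr_preset("I"), alpha = 1) {
  eq <- fhr_equilibrium(params)
  n <- length(times)
  states <- cbind(v = v,
                  w = if (is.null(w)) rep(eq$w_star, n) else w,
                  y = if (is.null(y)) rep(eq$y_star, n) else y)
  structure(list(times = times, states = states, params = params,
                 alpha = alpha, dt = times[2] - times[1],
                 n_steps = n - 1L, seed = NA_integer_,
                 perturbation_scale = 0, init = states[1, ],
                 engine = "cpp"),
            class = "fhr_trajectory")
}

# Random parameter set satisfying condition (A) (b*d < b + d).
random_params_A <- function() {
  repeat {
    b <- runif(1, 0.2, 2)
    d <- runif(1, 0.2, 2)
    if (b * d < b + d) break
  }
  suppressWarnings(fhr_params(a = runif(1, -1, 1), b = b,
                              c = runif(1, -1.5, 1.5), d = d,
                              delta = runif(1, 0.01, 0.5),
                              mu = runif(1, 1e-4, 0.5),
                              I = runif(1, -1, 4)))
}
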