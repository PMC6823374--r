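test_that("L1 weights: closed forms, empty case, telescoping identity", {
  expect_identical(l1_weights(1, 0.5), numeric(0))
  expect_equal(l1_weights(2, 0.5), sqrt(2) - 1)
  # alpha = 1: no memory at all
  expect_true(all(l1_weights(50, 1) == 0))
  # telescoping oracle: sum of weights is N^(1-alpha) - 1
  for (alpha in c(0.5, 0.8, 0.99))
    for (N in c(5, 10, 100, 1e4))
      expect_lt(abs(sum(l1_weights(N, alpha)) - (N^(1 - alpha) - 1)), 1e-9)
  # direct evaluation oracle at N = 5, alpha = 0.9
  k <- 0:3
  expect_equal(l1_weights(5, 0.9), (5 - k)^0.1 - (4 - k)^0.1)
})

test_that("at alpha = 1 the scheme is forward Euler on every preset", {
  for (lab in c("I", "II", "III", "IV", "V")) {
    p <- fhr_preset(lab)
    tr <- fhr_simulate(p, alpha = 1, n_steps = 1000, seed = 5,
                       perturbation_scale = 0.01)
    x <- tr$init
    f <- function(s) fhr_rhs(s, p)
    X <- matrix(NA_real_, 1001, 3)
    X[1, ] <- x
    for (i in 1:1000) {
      x <- x + 0.1 * f(x)
      X[i + 1, ] <- x
    }
    expect_lt(max(abs(X - unname(tr$states))), 1e-10)
  }
})

test_that("a zero field leaves the state constant for any alpha", {
  for (alpha in c(0.3, 0.7, 1)) {
    res <- caputo_integrate(function(x) c(0, 0), c(1.5, -2), alpha,
                            dt = 0.1, n_steps = 50)
    expect_true(all(res$states[, 1] == 1.5))
    expect_true(all(res$states[, 2] == -2))
  }
})

test_that("compiled and reference engines agree to machine precision", {
  p <- fhr_preset("I")
  a <- fhr_simulate(p, alpha = 0.9, n_steps = 300, seed = 5,
                    perturbation_scale = 0.01)
  b <- fhr_simulate(p, alpha = 0.9, n_steps = 300, seed = 5,
                    perturbation_scale = 0.01, engine = "r")
  expect_lt(max(abs(a$states - b$states)), 1e-12)
})

test_that("trajectories are deterministic given seed and config", {
  p <- fhr_preset("II")
  a <- fhr_simulate(p, alpha = 0.95, n_steps = 200, seed = 11)
  b <- fhr_simulate(p, alpha = 0.95, n_steps = 200, seed = 11)
  expect_identical(a$states, b$states)
  expect_identical(a$init, b$init)
  # times are uniform with spacing dt, starting at 0
  expect_equal(a$times, 0.1 * (0:200))
})

test_that("memory decomposition: identity, direct-sum route, alpha = 1", {
  p <- fhr_preset("I")
  tr <- fhr_simulate(p, alpha = 0.98, n_steps = 800, seed = 1)
  for (N in c(1, 2, 17, 800)) {
    md <- memory_decomposition(tr, N)
    # stored state is exactly markov - trace
    expect_lt(max(abs(md$markov_term - md$memory_trace - md$state)), 1e-10)
  }
  # the direct weighted sum agrees with the identity-route series
  ser <- memory_trace_series(tr)
  md <- memory_decomposition(tr, 800)
  expect_lt(abs(md$memory_trace[["v"]] - ser[800]), 1e-10)
  expect_error(memory_decomposition(tr, 0), "between 1 and")
  expect_error(memory_decomposition(tr, 801), "between 1 and")

  tr1 <- fhr_simulate(p, alpha = 1, n_steps = 400, seed = 1)
  expect_true(all(memory_trace_series(tr1) == 0))
  expect_equal(max(abs(memory_decomposition(tr1, 300)$memory_trace)), 0)
})

test_that("memory trace oscillates in the bursting regime and decays in the quiescent one", {
  p <- fhr_preset("I")
  tr <- fhr_simulate(p, alpha = 0.98, n_steps = 800, seed = 1)
  ser <- memory_trace_series(tr)
  expect_gt(max(abs(ser)), 0)
  expect_gt(sum(diff(sign(ser)) != 0), 0)  # sign changes present
  # below the critical exponent the state settles and the trace follows
  trc <- fhr_simulate(p, alpha = 0.79, t_end = 2000, seed = 1,
                      perturbation_scale = 0.01)
  s <- abs(memory_trace_series(trc))
  expect_lt(max(tail(s, 2000)), 0.05 * max(s))
})

test_that("the set-I system settles onto the printed fixed point below alpha*", {
  p <- fhr_preset("I")
  tr <- fhr_simulate(p, alpha = 0.79, t_end = 2000, seed = 1,
                     perturbation_scale = 0.01)
  vtail <- tail(tr$states[, "v"], 2000)
  expect_lt(abs(mean(vtail) - (-0.885098)), 0.01)
  expect_lt(diff(range(vtail)), 0.05)
})

test_that("halving the step shrinks the terminal-state change (L1 consistency)", {
  p <- fhr_preset("I")
  term <- vapply(c(0.1, 0.05, 0.025), function(h)
    unname(tail(fhr_simulate(p, alpha = 0.9, dt = h, t_end = 50, seed = 2,
                             perturbation_scale = 0.01)$states[, "v"], 1)),
    numeric(1))
  d <- abs(diff(term))
  expect_lt(d[2], d[1])
})

test_that("the divergence guard aborts with the offending step index", {
  err <- tryCatch(caputo_integrate(function(x) 1e5, 0, alpha = 1,
                                   dt = 0.1, n_steps = 10),
                  fhr_divergence = function(e) e)
  expect_s3_class(err, "fhr_divergence")
  expect_equal(err$step, 1L)
  # exponential blow-up trips the guard later but before the horizon
  err2 <- tryCatch(caputo_integrate(function(x) 2 * x, 1, alpha = 1,
                                    dt = 1, n_steps = 100),
                   fhr_divergence = function(e) e)
  expect_true(err2$step > 1 && err2$step < 100)
})

test_that("simulation without an init requires a seed", {
  expect_error(fhr_simulate(fhr_preset("I"), alpha = 1, n_steps = 10),
               "seed")
})
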