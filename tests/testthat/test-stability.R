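test_that("cubic invariants match hand-computed values for set I", {
  cf <- cubic_form(fhr_preset("I"))
  expect_equal(cf$p, -1.25)          # 1 - 1/0.8 - 1/1
  expect_equal(cf$q, -4.0125)        # 3*0.3125 - 3*0.875 + 3*(-0.775)
  # defining identity F(v*) = q at the equilibrium
  eq <- fhr_equilibrium(fhr_preset("I"))
  expect_lt(abs(cubic_F(eq$v_star, fhr_preset("I")) - cf$q), 1e-9)
})

test_that("analysis refuses parameter sets violating condition (A)", {
  p_bad <- suppressWarnings(fhr_params(b = 3, d = 2))
  expect_error(cubic_form(p_bad), "condition \\(A\\)")
  expect_error(fhr_equilibrium(p_bad), "condition \\(A\\)")
})

test_that("equilibrium back-substitution is consistent", {
  for (lab in c("I", "III", "V")) {
    p <- fhr_preset(lab)
    eq <- fhr_equilibrium(p)
    expect_equal(eq$w_star, (eq$v_star + p$a) / p$b)
    expect_equal(eq$y_star, (p$c - eq$v_star) / p$d)
  }
})

test_that("characteristic-polynomial roots match Jacobian eigenvalues on random sets", {
  set.seed(2024)
  for (i in 1:100) {
    p <- random_params_A()
    # eigen_spectrum enforces route agreement to 1e-8 internally; recheck
    # against a direct eigendecomposition here as an external oracle
    sp <- eigen_spectrum(p)
    evJ <- eigen(fhr_jacobian(sp$equilibrium$v_star, p),
                 only.values = TRUE)$values
    d <- vapply(as.complex(evJ),
                function(z) min(Mod(z - sp$values)), numeric(1))
    expect_lt(max(d), 1e-8)
    # Vieta: sum and product of the roots
    expect_lt(abs(sum(Re(sp$values)) - sp$trace_J),
              1e-8 * max(1, abs(sp$trace_J)))
    expect_lt(Mod(prod(sp$values) - sp$det_J),
              1e-8 * max(1, abs(sp$det_J)))
    # at least one root is real and negative (det < 0 under condition A)
    expect_lt(sp$lambda1, 0)
  }
})

test_that("stability is alpha-independent outside the current window (oracle)", {
  p <- fhr_preset("I")
  ais <- alpha_independent_stability(p)
  set.seed(99)
  lows <- ais$I_low - runif(25, 0.01, 2)
  highs <- ais$I_high + runif(25, 0.01, 2)
  for (I in c(lows, highs)) {
    p2 <- p
    p2$I <- I
    expect_true(all(Re(eigen_spectrum(p2)$values) < 0))
  }
})

test_that("the two printed forms of the critical exponent agree on all presets", {
  for (lab in c("I", "II", "III", "V")) {
    p <- fhr_preset(lab)
    sp <- eigen_spectrum(p)
    a_arg <- (2 / pi) * abs(Arg(sp$pair[1]))
    ratio <- (sp$trace_J - sp$lambda1) * sqrt(-sp$lambda1) /
      (2 * sqrt(-sp$det_J))
    a_acos <- (2 / pi) * acos(min(1, max(-1, ratio)))
    expect_lt(abs(a_arg - a_acos), 1e-6)
    expect_equal(critical_alpha(p, sp), a_arg)
  }
})

test_that("all-real spectra yield no fractional Hopf threshold", {
  p <- fhr_preset("IV")
  sp <- eigen_spectrum(p)
  expect_false(sp$has_pair)
  expect_gt(sp$discriminant, 0)
  expect_true(is.na(critical_alpha(p, sp)))
  expect_true(is.na(chaos_alpha(p, sp)))
  expect_false(is_saddle_focus_index2(p, sp))
})

test_that("saddle-focus classification and the n-index stability rule", {
  p <- fhr_preset("I")
  sp <- eigen_spectrum(p)
  expect_true(is_saddle_focus_index2(p, sp))
  astar <- critical_alpha(p, sp)
  # n_i < 0 for every eigenvalue iff alpha below alpha*
  expect_true(all(n_index(astar - 0.05, sp$values) < 0))
  expect_true(any(n_index(astar + 0.05, sp$values) > 0))
  # a negative real eigenvalue has |arg| = pi: stable for every alpha <= 1
  expect_true(all(n_index(1, sp$lambda1) < 0))
})

test_that("the real root localization follows the sign of Q(-mu)", {
  # with d = 1, Q(-mu) = mu (b delta - mu): mu < b*delta places lambda1
  # below -mu, otherwise in [-mu, 0)
  for (lab in c("I", "II")) {
    p <- fhr_preset(lab)
    expect_true(p$mu < p$b * p$delta)
    expect_lt(eigen_spectrum(p)$lambda1, -p$mu)
  }
  pIII <- fhr_preset("III")
  expect_true(pIII$mu > pIII$b * pIII$delta)
  l1 <- eigen_spectrum(pIII)$lambda1
  expect_true(l1 >= -pIII$mu && l1 < 0)
})

test_that("trace-zero and continuation Hopf currents bracket the printed symmetry", {
  p <- fhr_preset("I")
  tz <- classical_hopf_currents(p, "trace_zero")
  ct <- classical_hopf_currents(p, "continuation")
  # odd symmetry of the cubic: HB1 + HB2 = 2(a/b - c/d)
  s <- 2 * (p$a / p$b - p$c / p$d)
  expect_lt(abs(sum(tz) - s), 1e-3)
  expect_lt(abs(sum(ct) - s), 1e-3)
  # the continuation crossing sits slightly below the trace-zero estimate
  expect_lt(ct[["HB1"]], tz[["HB1"]])
  expect_gt(ct[["HB2"]], tz[["HB2"]])
})

test_that("hopf curve reports alpha* on the scanned grid and masks the all-real band", {
  p <- fhr_preset("I")
  hc <- hopf_curve(p, c(0.3125, 0.4, 1.0, 2.0))
  expect_equal(hc$alpha_star[1], 0.80828, tolerance = 1e-4)
  expect_equal(hc$alpha_star[2], 0.6951, tolerance = 1e-4)
  expect_true(all(hc$masked[3:4]))
  expect_true(all(is.na(hc$alpha_star[3:4])))
})

test_that("stability report bundles the headline quantities coherently", {
  rep <- stability_report(fhr_preset("I"))
  expect_equal(unname(rep$equilibrium["v"]), -0.885098, tolerance = 1e-5)
  expect_equal(rep$critical_alpha, rep$chaos_alpha)
  expect_true(rep$saddle_focus_index2)
  expect_false(rep$alpha_independent)
  expect_equal(rep$gamma1, -rep$gamma2)
  expect_equal(rep$F_gamma1, -rep$F_gamma2)
})
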