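test_that("time renormalization divides times by radius and nothing else", {
  tc <- time_course(c(0, 5, 10), c(3, 2, 1), R_um = 2)
  rn <- renormalize_time(tc)
  expect_equal(rn$time, c(0, 2.5, 5))
  expect_equal(rn$value, tc$value)
  expect_equal(rn$time_units, "min_per_um")
  # R = 1 is the identity on times
  rn1 <- renormalize_time(time_course(c(0, 5, 10), c(3, 2, 1), R_um = 1))
  expect_equal(rn1$time, c(0, 5, 10))
  expect_true(all(diff(rn$time) > 0))
  expect_error(renormalize_time(time_course(0:2, 1:3, R_um = 0)), "radius")
})

test_that("decay onset is the smoothed maximum, earliest on ties", {
  t <- seq(0, 95, by = 5)
  expect_equal(detect_decay_onset(time_course(t, exp(-t / 30))), 1)
  # rise then fall peaking at sample 5
  v <- c(1, 2, 3, 4, 5, 4.5, 4, 3.5, 3, 2.5, 2, 1.5, 1, 0.9, 0.8, 0.7,
         0.6, 0.5, 0.4, 0.3)
  expect_equal(detect_decay_onset(time_course(t, v)), 5)
  expect_equal(detect_decay_onset(time_course(t, rep(2, 20))), 1)
  expect_error(detect_decay_onset(time_course(0:3, 1:4)), "at least 5")
})

test_that("exponential fits recover generating parameters exactly", {
  t <- seq(0, 150, by = 5)
  tc <- time_course(t, 2 * exp(-t / 30) + 1, R_um = 2)
  fit <- fit_exponential_decay(tc)
  expect_equal(fit$A, 2, tolerance = 1e-6)
  expect_equal(fit$tau, 30, tolerance = 1e-6)
  expect_equal(fit$B, 1, tolerance = 1e-6)
  expect_false(fit$censored)
  expect_true(fit$converged)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "tau"], 30, tolerance = 1e-6)
  expect_equal(glance(fit)$rms, 0, tolerance = 1e-6)
})

test_that("a constant curve is flagged: amplitude zero, tau unidentifiable", {
  t <- seq(0, 100, by = 5)
  fit <- fit_exponential_decay(time_course(t, rep(3, length(t))))
  expect_true(fit$censored)
})

test_that("fits are invariant to affine intensity rescaling", {
  t <- seq(0, 150, by = 5)
  v <- 2 * exp(-t / 40) + 1
  f1 <- fit_exponential_decay(time_course(t, v))
  f2 <- fit_exponential_decay(time_course(t, 5 * v + 3))
  expect_equal(f2$tau, f1$tau, tolerance = 1e-6)
  expect_equal(f2$A, 5 * f1$A, tolerance = 1e-6)
  expect_equal(f2$B, 5 * f1$B + 3, tolerance = 1e-6)
})

test_that("noisy fits are unbiased with calibrated confidence intervals", {
  # Monte-Carlo against the generating model: 200 seeded replicates with
  # sigma = 0.05 A; median tau within 5% of truth, ~95% CI coverage
  set.seed(1234)
  t <- seq(0, 150, by = 5)
  truth <- list(A = 2, B = 1, tau = 30)
  n_rep <- 200
  taus <- numeric(n_rep)
  cover <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    v <- truth$A * exp(-t / truth$tau) + truth$B +
      stats::rnorm(length(t), 0, 0.05 * truth$A)
    fit <- fit_exponential_decay(time_course(t, v), onset = 1L)
    taus[i] <- fit$tau
    se <- sqrt(fit$vcov["tau", "tau"])
    cover[i] <- abs(fit$tau - truth$tau) <= 1.96 * se
  }
  expect_lt(abs(stats::median(taus) - truth$tau) / truth$tau, 0.05)
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("the censoring rule flags fast and plateau-started decays", {
  cfg <- analysis_config()
  t <- seq(0, 60, by = 2)   # renormalized time, min/um
  # tau = 4 min/um < 10: censored
  f_fast <- fit_exponential_decay(
    time_course(t, 2 * exp(-t / 4) + 1, time_units = "min_per_um"))
  f_fast <- censor_fast_decays(f_fast, cfg$censor_threshold_min_per_um)
  expect_true(f_fast$censored)
  # tau = 30 min/um with the full decay observed: kept
  t2 <- seq(0, 150, by = 5)
  f_slow <- censor_fast_decays(fit_exponential_decay(
    time_course(t2, 2 * exp(-t2 / 30) + 1, time_units = "min_per_um")))
  expect_false(f_slow$censored)
  # a curve already at its plateau when observation begins is censored
  # regardless of tau: absolute time starts long after the decay
  t3 <- seq(120, 270, by = 5)
  f_late <- censor_fast_decays(fit_exponential_decay(
    time_course(t3, 2 * exp(-t3 / 30) + 1, time_units = "min_per_um")))
  expect_equal(f_late$tau, 30, tolerance = 1e-3)
  expect_true(f_late$censored)
})

test_that("collapse statistics separate surface from volume processes", {
  # identical tau/R: zero dispersion after renormalization
  radii <- c(1, 1.5, 2, 3, 4)
  kappa <- 0.02
  fits <- lapply(radii, function(R) {
    t <- seq(0, 300, by = 5)
    fit_exponential_decay(
      time_course(t, exp(-t / (R / (3 * kappa))) + 0.1, R_um = R))
  })
  cq <- collapse_quality(fits)
  expect_lt(cq$cv_renormalized, 1e-6)
  expect_gt(cq$tau_span, 3.99)
  expect_equal(cq$slope_raw, 1 / (3 * kappa), tolerance = 1e-3)
  # radius-independent decay (e.g. photobleaching): renormalization must
  # NOT collapse it - dispersion increases instead
  fits_vol <- lapply(radii, function(R) {
    t <- seq(0, 300, by = 5)
    fit_exponential_decay(time_course(t, exp(-t / 40) + 0.1, R_um = R))
  })
  tau_raw <- vapply(fits_vol, `[[`, numeric(1), "tau")
  ratio <- tau_raw / radii
  cv_raw <- stats::sd(tau_raw) / mean(tau_raw)
  cv_rn <- stats::sd(ratio) / mean(ratio)
  expect_lt(cv_raw, cv_rn)
  expect_error(collapse_quality(fits[1:2]), "at least 3")
  expect_error(collapse_quality(fits, radii = c(1, 1.1, 1.2, 1.3, 1.4)),
               "spread")
})
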