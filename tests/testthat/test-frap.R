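frap_fixture <- function() fixture("frap_fx", function() frap_stack(D = 0.2))

droplet_midplane_mask <- function(fx) {
  d <- fx$droplet
  px <- fx$stack$pixel_size_um
  ny <- dim(fx$stack$data)[4]; nx <- dim(fx$stack$data)[5]
  xs <- (seq_len(nx) - 1) * px
  ys <- (seq_len(ny) - 1) * px
  outer((ys - d$y_um)^2, (xs - d$x_um)^2, "+") <= d$R_um^2
}

test_that("bleach spots are located within a pixel of ground truth", {
  fx <- frap_fixture()
  dmask <- droplet_midplane_mask(fx)
  spot <- locate_bleach_spot(fx$stack, dmask, fx$z_mid, fx$bleach_frame)
  expect_lte(max(abs(spot$center_px - fx$center_px)), 1)
  # restricting the search to a nominal center works too
  spot2 <- locate_bleach_spot(fx$stack, dmask, fx$z_mid, fx$bleach_frame,
                              nominal_center_px = fx$center_px)
  expect_lte(max(abs(spot2$center_px - fx$center_px)), 1)
  # an unbleached droplet raises "no bleach detected"
  expect_error(
    locate_bleach_spot(fx$stack, dmask, fx$z_mid, 3L),
    "no bleach"
  )
})

test_that("intensity ratios cancel global drift and report spot depth", {
  # synthetic single-droplet stack with a known half-intensity spot
  n <- 41L
  ctr <- 21L
  dmask <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+") <= 15^2
  spot <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+") <= 1.5^2
  base <- matrix(0.1, n, n); base[dmask] <- 100
  half <- base; half[spot] <- 50
  arr <- array(0, dim = c(3, 1, 1, n, n))
  arr[1, 1, 1, , ] <- base
  arr[2, 1, 1, , ] <- half
  arr[3, 1, 1, , ] <- half * 0.8   # global 20% intensity drop
  st <- image_stack(arr, pixel_size_um = 0.14, frame_interval_min = 0.1,
                    channel_names = "RNA")
  rs <- intensity_ratio_series(st, spot, dmask, z = 1, channel = "RNA")
  expect_equal(rs$ratio[1], 1, tolerance = 1e-12)
  expect_equal(rs$ratio[2], 0.5, tolerance = 1e-12)
  expect_equal(rs$ratio[3], 0.5, tolerance = 1e-12)  # drift cancels
  # spot must be inside the droplet, and the reference must be nonempty
  out_spot <- outer((seq_len(n) - 3)^2, (seq_len(n) - 3)^2, "+") <= 1.5^2
  expect_error(intensity_ratio_series(st, out_spot, dmask, 1, "RNA"),
               "inside")
  tiny <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+") <= 2^2
  expect_error(intensity_ratio_series(st, spot, tiny, 1, "RNA"), "reference")
})

test_that("the affine normalization is exactly the stated formula", {
  # I_i = 0.9, I(0) = 0.3, I(t) = 0.6 -> N = 0.5
  ratios <- tibble::tibble(frame = 1:5, time_min = (0:4) * 0.1,
                           ratio = c(0.9, 0.9, 0.3, 0.6, 0.9))
  rec <- normalize_frap(ratios, bleach_frame = 3L)
  expect_identical(rec$N[1], 0)              # N(0) = 0 exactly
  expect_equal(rec$N[2], 0.5)                # (0.6 - 0.3) / (0.9 - 0.3)
  expect_equal(rec$N[3], 1)                  # full recovery
  expect_equal(rec$I_i, 0.9)
  # I_i <= I(0) is not a bleach
  bad <- tibble::tibble(frame = 1:5, time_min = (0:4) * 0.1,
                        ratio = c(0.5, 0.5, 0.7, 0.8, 0.9))
  expect_error(normalize_frap(bad, 3L), "invalid bleach")
})

test_that("field-of-view averaging uses the sample standard deviation", {
  mk <- function(N) structure(list(time = 0:3, N = N, ratio = N,
                                   I_i = 1, I0 = 0, bleach_frame = 2L,
                                   experiment_time_min = 10),
                              class = "frap_record")
  avg <- average_field_of_view(list(mk(rep(0, 4)), mk(rep(1, 4))))
  expect_true(all(avg$mean == 0.5))
  expect_true(all(abs(avg$sd - sqrt(0.5)) < 1e-12))
  avg1 <- average_field_of_view(list(mk(c(0, 0.5, 0.8, 0.9))))
  expect_true(all(is.na(avg1$sd)))           # single curve: sd undefined
  expect_equal(avg1$mean, c(0, 0.5, 0.8, 0.9))
  ident <- average_field_of_view(list(mk(rep(0.3, 4)), mk(rep(0.3, 4))))
  expect_true(all(ident$sd == 0))
  bad <- mk(rep(0, 4)); bad$time <- c(0, 1, 2, 4)
  expect_error(average_field_of_view(list(mk(rep(0, 4)), bad)), "time base")
})

test_that("recovery fits return generating parameters and flag flat curves", {
  t <- seq(0, 2, by = 0.05)
  curve <- tibble::tibble(time = t, mean = 0.8 * (1 - exp(-t / 0.2)))
  fit <- fit_recovery(curve)
  expect_equal(fit$M, 0.8, tolerance = 1e-6)
  expect_equal(fit$tau_rec, 0.2, tolerance = 1e-6)
  expect_false(fit$flagged)
  flat <- fit_recovery(tibble::tibble(time = t, mean = rep(0, length(t))))
  expect_true(flat$flagged)
  g <- glance(fit)
  expect_equal(g$M, 0.8, tolerance = 1e-6)
})

test_that("end-to-end FRAP measurement recovers diffusive recovery", {
  fx <- frap_fixture()
  rec <- measure_frap_event(fx$stack, fx$bleach_frame,
                            nominal_center_px = fx$center_px)
  expect_identical(rec$N[1], 0)
  expect_gt(rec$I_i, rec$I0)
  # recovery approaches a plateau below 1 (bleached material is lost)
  n <- length(rec$N)
  tail_mean <- mean(rec$N[(n - 5):n])
  expect_gt(tail_mean, 0.5)
  expect_lt(tail_mean, 1.05)
  fit <- fit_recovery(tibble::tibble(time = rec$time, mean = rec$N))
  expect_false(fit$flagged)
  expect_gt(fit$tau_rec, 0)
})

test_that("fitted recovery timescale decreases with diffusivity", {
  Ds <- c(0.05, 0.15, 0.45)
  taus <- vapply(Ds, function(D) {
    fx <- frap_stack(D = D, n_frames = 60, frame_interval_min = 0.02 / D)
    rec <- measure_frap_event(fx$stack, fx$bleach_frame,
                              nominal_center_px = fx$center_px)
    fit_recovery(tibble::tibble(time = rec$time, mean = rec$N))$tau_rec
  }, numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("aging series orders experiments and exposes slowdowns", {
  mkfit <- function(tau, t_exp) structure(
    list(M = 0.8, tau_rec = tau, rms = 0, converged = TRUE, flagged = FALSE,
         n_points = 10L, n_droplets = 3L, experiment_time_min = t_exp,
         time = 0:9, value = rep(0, 10)),
    class = "recovery_fit")
  fits <- list(mkfit(0.9, 60), mkfit(0.3, 10), mkfit(0.5, 30))
  ag <- aging_series(fits)
  expect_equal(ag$experiment_time_min, c(10, 30, 60))
  expect_equal(ag$tau_rec_min, c(0.3, 0.5, 0.9))
  expect_true(all(diff(ag$tau_rec_min) > 0))
  single <- aging_series(fits[1])
  expect_equal(nrow(single), 1)
})
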