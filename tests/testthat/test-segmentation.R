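test_that("segmentation finds each rendered droplet exactly once", {
  fx <- small_scene()
  labels <- segment_frame(fx$noisy$stack, 1)
  ids <- setdiff(unique(as.integer(labels)), 0L)
  expect_equal(length(ids), 3)
  sc <- fx$scene
  hit <- integer(0)
  for (i in seq_len(3)) {
    d <- sc$droplets[i, ]
    iz <- round(d$z_um / sc$z_step_um) + 1
    iy <- round(d$y_um / sc$pixel_size_um) + 1
    ix <- round(d$x_um / sc$pixel_size_um) + 1
    hit <- c(hit, labels[iz, iy, ix])
  }
  # every ground-truth center is inside a distinct label: no merges, even
  # for droplets separated by only a little over 2 PSF sigma
  expect_true(all(hit > 0))
  expect_equal(length(unique(hit)), 3)
})

test_that("a blank frame yields an empty labeling, not an error", {
  st <- image_stack(array(5, dim = c(1, 3, 1, 20, 20)),
                    pixel_size_um = 0.14, frame_interval_min = 5,
                    channel_names = "protein")
  labels <- segment_frame(st, 1)
  expect_true(all(labels == 0))
})

test_that("recovered radii match ground truth within max(1 px, psf sigma)", {
  fx <- small_scene()
  tr <- track_droplets(fx$noisy$stack)
  s <- track_summary(tr)
  sc <- fx$scene
  tol <- max(sc$pixel_size_um, sc$params$psf_sigma_um)
  truth <- sort(sc$droplets$R_um)
  got <- sort(s$R_um)
  expect_equal(length(got), length(truth))
  expect_true(all(abs(got - truth) <= tol))
})

test_that("midplane selection maximizes slice area with lowest-z ties", {
  # voxelized sphere spanning z = 2..8 peaks at its equator z = 5
  sph <- array(FALSE, dim = c(9, 21, 21))
  for (z in 1:9) for (y in 1:21) for (x in 1:21)
    sph[z, y, x] <- (z - 5)^2 + ((y - 11) / 3)^2 + ((x - 11) / 3)^2 <= 9
  expect_equal(select_midplane(sph), 5)
  # hemisphere, flat side down (z = 4..8): area is monotone decreasing
  hemi <- array(FALSE, dim = c(9, 21, 21))
  for (z in 4:8) for (y in 1:21) for (x in 1:21)
    hemi[z, y, x] <- ((y - 11)^2 + (x - 11)^2) <= (25 - (z - 4)^2 * 25 / 16)
  expect_equal(select_midplane(hemi), 4)
  # two-z plateau of equal area resolves to the lower z
  plat <- array(FALSE, dim = c(4, 5, 5))
  plat[2, 2:4, 2:4] <- TRUE
  plat[3, 2:4, 2:4] <- TRUE
  expect_equal(select_midplane(plat), 2)
  expect_error(select_midplane(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("measurements on ideal shapes behave as closed forms dictate", {
  dk <- disk_image(20, value = 100)
  labels <- array(0L, dim = c(1, dk$n, dk$n))
  labels[1, , ] <- dk$mask * 1L
  st <- image_stack(array(dk$img, dim = c(1, 1, 1, dk$n, dk$n)),
                    pixel_size_um = 0.14, frame_interval_min = 5,
                    channel_names = "protein")
  obs <- measure_observation(labels, st, 1, 1L)
  expect_equal(obs$center_I_protein, 100)            # uniform disk center
  expect_gte(obs$circularity, 0.95)                  # disk passes the filter
  expect_equal(obs$radius_um, sqrt(sum(dk$mask) * 0.14^2 / pi))
  # centroid lands on the true disk center (0-based pixel-center coords)
  expect_equal(obs$x_um, (dk$center_px[1] - 1) * 0.14, tolerance = 1e-9)

  # a square scores near 4*pi*A/P^2 = pi/4 and fails the 0.9 filter
  n <- 36L
  sq <- matrix(0, n, n); sq[9:28, 9:28] <- 1
  labels2 <- array(0L, dim = c(1, n, n)); labels2[1, , ] <- sq
  st2 <- image_stack(array(sq * 50, dim = c(1, 1, 1, n, n)),
                     pixel_size_um = 0.14, frame_interval_min = 5,
                     channel_names = "protein")
  obs2 <- measure_observation(labels2, st2, 1, 1L)
  expect_lt(obs2$circularity, 0.9)
  expect_gt(obs2$circularity, pi / 4 - 0.1)

  # a region touching the border is flagged
  labels3 <- array(0L, dim = c(1, 10, 10)); labels3[1, 1:4, 3:6] <- 1L
  st3 <- image_stack(array(1, dim = c(1, 1, 1, 10, 10)),
                     pixel_size_um = 0.14, frame_interval_min = 5,
                     channel_names = "protein")
  expect_true(measure_observation(labels3, st3, 1, 1L)$border)
})

test_that("radial profiles reproduce analytic bin averages", {
  cfg <- analysis_config()
  # uniform disk: every populated bin averages to the disk value
  dk <- disk_image(14, value = 7)
  prof <- radial_profile(dk$img, centroid_um = (dk$center_px - 1) * 0.14,
                         R_um = 14 * 0.14, pixel_size_um = 0.14,
                         radial_bin_um = cfg$radial_bin_um)
  pop <- prof[prof$n_px > 0, ]
  expect_true(all(abs(pop$mean_intensity - 7) < 1e-9))

  # bin count: R = 2 um at 0.24 um bins -> ceil(2 / 0.24) = 9 bins
  dk2 <- disk_image(15)
  prof2 <- radial_profile(dk2$img, (dk2$center_px - 1) * 0.14, R_um = 2,
                          pixel_size_um = 0.14, radial_bin_um = 0.24)
  expect_equal(nrow(prof2), 9)
  expect_true(all(prof2$n_px > 0))

  # quadratic profile C0 (1 - r^2 / (2 R^2)): bin means match the
  # pixel-exact average of the analytic field over each annulus within 1%
  R <- 2; px <- 0.14
  r_px <- ceiling(R / px)
  n <- 2L * r_px + 13L; c0 <- r_px + 7L
  xs <- (seq_len(n) - c0) * px
  rr <- sqrt(outer(xs^2, xs^2, "+"))
  img <- ifelse(rr <= R, 1 - rr^2 / (2 * R^2), 0)
  prof3 <- radial_profile(img, c((c0 - 1) * px, (c0 - 1) * px), R_um = R,
                          pixel_size_um = px, radial_bin_um = 0.24)
  # oracle: area-weighted analytic mean over the annulus [r1, r2):
  # mean = 1 - (r2^2 + r1^2) / (4 R^2)  (from integrating C(r) r dr)
  r1 <- prof3$r_lo_um; r2 <- r1 + 0.24
  r2c <- pmin(r2, R)   # outermost bin is clipped by the droplet edge
  analytic <- 1 - (r2c^2 + r1^2) / (4 * R^2)
  ok <- prof3$n_px > 30     # bins with enough pixels for the 1% claim
  expect_true(all(abs(prof3$mean_intensity[ok] - analytic[ok]) /
                    analytic[ok] < 0.01))
  expect_error(radial_profile(img, c(-1, 0), R, px), "outside")
})
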