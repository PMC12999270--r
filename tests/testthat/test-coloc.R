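test_that("the mask mean of the ncorr map is exactly the Pearson r", {
  set.seed(11)
  n <- 60L
  A <- matrix(stats::runif(n * n), n, n)
  B <- 0.4 * A + matrix(stats::rnorm(n * n, 0, 0.2), n, n) + 1
  mask <- outer((seq_len(n) - 30)^2, (seq_len(n) - 30)^2, "+") <= 25^2
  map <- ncorr_map(A, B, mask)
  expect_equal(mean(map[mask]), stats::cor(A[mask], B[mask]),
               tolerance = 1e-12)
  # perfectly correlated and anti-correlated channels
  expect_equal(mean(ncorr_map(A, A, mask)[mask]), 1, tolerance = 1e-12)
  expect_equal(mean(ncorr_map(A, 3 - A, mask)[mask]), -1, tolerance = 1e-12)
  expect_true(all(is.na(map[!mask])))
  expect_error(ncorr_map(A, matrix(2, n, n), mask), "constant")
})

test_that("permuted channels decorrelate to the null level", {
  set.seed(21)
  n <- 100L
  A <- matrix(stats::runif(n * n), n, n)
  mask <- matrix(TRUE, n, n)
  Bp <- matrix(sample(A), n, n)
  r <- mean(ncorr_map(A, Bp, mask)[mask])
  expect_lt(abs(r), 3 / sqrt(n * n))
})

test_that("the map is affine-invariant with a normalization-free sign", {
  set.seed(31)
  n <- 40L
  A <- matrix(stats::runif(n * n), n, n)
  B <- matrix(stats::runif(n * n), n, n)
  mask <- matrix(TRUE, n, n)
  m1 <- ncorr_map(A, B, mask)
  m2 <- ncorr_map(2.5 * A + 7, B, mask)       # positive affine in A
  expect_equal(m1, m2, tolerance = 1e-12)
  m3 <- ncorr_map(A, 0.3 * B + 2, mask)
  expect_equal(m1, m3, tolerance = 1e-12)
  # pixel signs equal the signs of the raw product of mean deviations
  raw <- (A - mean(A)) * (B - mean(B))
  expect_true(all(sign(m1) == sign(raw)))
})

test_that("puncta segmentation finds bright features only", {
  n <- 61L
  mask <- outer((seq_len(n) - 31)^2, (seq_len(n) - 31)^2, "+") <= 25^2
  # uniform RNA: no puncta
  expect_true(all(segment_puncta(matrix(5, n, n) + 0 * mask, mask) == 0))
  # one bright Gaussian inside the droplet
  g <- 10 * exp(-(outer((seq_len(n) - 25)^2, (seq_len(n) - 28)^2, "+")) / 18)
  img <- matrix(5, n, n) + g
  lab <- segment_puncta(img, mask)
  expect_equal(max(lab), 1)
  expect_gt(lab[25, 28], 0)   # the peak lies inside the component
})

test_that("injected puncta are detected and anti-correlate with protein", {
  p <- synthetic_params(D_rna = 10, kappa = 0, psf_sigma_um = 0.1,
                        protein_accum_rate = 0, rng_seed = 8)
  sc <- make_scene(1, field_size_um = 10, params = p, seed = 8, radii = 2.5,
                   n_frames = 2)
  sc$puncta <- dplyr::bind_rows(
    punctum(1, onset_frame = 2, amplitude = 3, sigma_um = 0.3,
            protein_depletion = 0.5),
    punctum(1, onset_frame = 2, x_um = sc$droplets$x_um[1] + 1.1,
            y_um = sc$droplets$y_um[1] - 0.4, amplitude = 3,
            sigma_um = 0.25, protein_depletion = 0.5)
  )
  rn <- render_scene(sc, noise = FALSE)
  res <- colocalize_frame(rn$stack, 2)
  expect_equal(nrow(res$droplets), 1)
  expect_equal(res$droplets$n_puncta, 2)
  # noiseless depletion: each punctum sits in negatively correlated pixels
  expect_true(all(res$puncta$mean_ncorr < 0))
  expect_true(all(res$puncta$frac_negative > 0.9))
  # before the onset frame there are no puncta
  res1 <- colocalize_frame(rn$stack, 1)
  expect_equal(res1$droplets$n_puncta, 0)
})

test_that("puncta with no protein depletion leave protein untouched", {
  p <- synthetic_params(D_rna = 10, kappa = 0, psf_sigma_um = 0,
                        protein_accum_rate = 0, rng_seed = 9)
  sc <- make_scene(1, field_size_um = 8, params = p, seed = 9, radii = 2,
                   n_frames = 2)
  rn0 <- render_scene(sc, noise = FALSE)
  sc$puncta <- punctum(1, onset_frame = 2, amplitude = 2, sigma_um = 0.3,
                       protein_depletion = 0)
  rn1 <- render_scene(sc, noise = FALSE)
  expect_equal(rn1$stack$data[, , 2, , ], rn0$stack$data[, , 2, , ],
               tolerance = 1e-12)                       # protein unchanged
  expect_gt(max(rn1$stack$data[2, , 1, , ] - rn0$stack$data[2, , 1, , ]), 0)
  # with independent noise and no depletion, per-punctum ncorr sits at the
  # permutation-null level
  set.seed(5)
  n <- 61L
  mask <- outer((seq_len(n) - 31)^2, (seq_len(n) - 31)^2, "+") <= 25^2
  A <- matrix(stats::rnorm(n * n, 10, 1), n, n)
  B <- matrix(stats::rnorm(n * n, 10, 1), n, n)
  lab <- matrix(0L, n, n); lab[25:31, 25:31] <- 1L
  ov <- summarize_overlap(lab, ncorr_map(A, B, mask))
  null_sd <- 1 / sqrt(sum(lab == 1L))
  expect_lt(abs(ov$mean_ncorr), 3 * null_sd)
  # no puncta: empty table
  empty <- summarize_overlap(matrix(0L, n, n), ncorr_map(A, B, mask))
  expect_equal(nrow(empty), 0)
})
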