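# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small noiseless 3-droplet scene plus render, reused by segmentation,
# tracking and colocalization tests.
small_scene <- function() fixture("small_scene", function() {
  p <- synthetic_params(D_rna = 10, kappa = 0.01, psf_sigma_um = 0.15,
                        rng_seed = 42, photon_scale = photon_scale_for_snr(10))
  sc <- make_scene(3, field_size_um = 14, params = p, seed = 42,
                   radii = c(2.4, 1.6, 1.1), n_frames = 3, z_step_um = 0.5)
  list(scene = sc,
       noiseless = render_scene(sc, noise = FALSE),
       noisy = render_scene(sc))
})

# Rasterized disk mask of radius r px, centered in a square image.
disk_image <- function(r_px, pad = 6L, value = 1) {
  n <- 2L * r_px + 2L * pad + 1L
  c0 <- r_px + pad + 1L
  m <- outer(seq_len(n), seq_len(n),
             function(y, x) ((x - c0)^2 + (y - c0)^2) <= r_px^2)
  list(mask = m, img = m * value, center_px = c(c0, c0), n = n)
}

# Single-droplet FRAP recording: static droplet (kappa = 0), fast frames,
# bleach at a given frame, rendered noiselessly. Returns stack + geometry.
frap_stack <- function(D, depth = 0.8, n_frames = 60,
                       frame_interval_min = 0.1, bleach_frame = 5L,
                       R_um = 2, sigma_um = 0.21, seed = 7) {
  p <- synthetic_params(D_rna = D, kappa = 0, psf_sigma_um = 0,
                        protein_accum_rate = 0, rng_seed = seed)
  sc <- make_scene(1, field_size_um = 8, params = p, seed = seed,
                   radii = R_um, n_frames = n_frames,
                   frame_interval_min = frame_interval_min, z_step_um = 0.5)
  rn <- render_scene(sc, noise = FALSE)
  ev <- frap_event(frame = bleach_frame, droplet_id = 1,
                   sigma_um = sigma_um, depth = depth)
  st <- apply_frap_event(rn$stack, sc, ev)
  d <- sc$droplets[1, ]
  list(stack = st, scene = sc, droplet = d, bleach_frame = bleach_frame,
       center_px = c(y = round(d$y_um / sc$pixel_size_um) + 1L,
                     x = round(d$x_um / sc$pixel_size_um) + 1L),
       z_mid = round(d$z_um / sc$z_step_um) + 1L)
}

# Independent fine-grid FRAP oracle: explicit 2-D diffusion of the bleach
# field inside a disk on a 0.035 um grid (4x finer than the rendered
# pixels), independent of apply_frap_event's implementation. Returns the
# spot-mean recovery curve at the requested frame times.
frap_oracle_curve <- function(D, R_um, sigma_um, depth, times_min,
                              spot_radius_um, h_um = 0.035) {
  n <- 2L * ceiling(R_um / h_um) + 5L
  c0 <- (n + 1) / 2
  xs <- (seq_len(n) - c0) * h_um
  r2 <- outer(xs^2, xs^2, "+")
  mask <- r2 <= R_um^2
  b <- matrix(1, n, n)
  g <- exp(-r2 / (2 * sigma_um^2))
  b[mask] <- 1 - depth * g[mask]
  spot <- mask & (r2 <= spot_radius_um^2)
  mnum <- mask * 1
  dt <- 0.2 * h_um^2 / max(D, 1e-12)
  out <- numeric(length(times_min))
  t_now <- 0
  out[1] <- mean(b[spot])
  for (k in 2:length(times_min)) {
    n_steps <- ceiling((times_min[k] - t_now) / dt)
    dtk <- (times_min[k] - t_now) / n_steps
    lam <- D * dtk / h_um^2
    for (s in seq_len(n_steps)) {
      bm <- b * mnum
      up <- rbind(bm[-1, ], 0); down <- rbind(0, bm[-n, ])
      left <- cbind(bm[, -1], 0); right <- cbind(0, bm[, -n])
      nup <- rbind(mnum[-1, ], 0); ndown <- rbind(0, mnum[-n, ])
      nleft <- cbind(mnum[, -1], 0); nright <- cbind(0, mnum[, -n])
      nb <- nup + ndown + nleft + nright
      bn <- b + lam * ((up + down + left + right) - nb * b)
      bn[!mask] <- b[!mask]
      b <- bn
    }
    t_now <- times_min[k]
    out[k] <- mean(b[spot])
  }
  out
}

# Half-time of a recovery trace toward its final value.
recovery_half_time <- function(times, values) {
  v0 <- values[1]
  vf <- values[length(values)]
  target <- v0 + 0.5 * (vf - v0)
  i <- which(values >= target)[1]
  if (is.na(i) || i == 1) return(NA_real_)
  # linear interpolation between the bracketing samples
  t1 <- times[i - 1]; t2 <- times[i]
  v1 <- values[i - 1]; v2 <- values[i]
  t1 + (target - v1) / (v2 - v1) * (t2 - t1)
}

# End-to-end surface-departure experiment shared by the acceptance tests:
# five radii spanning 1-4 um, SNR 10, rendered with noise, tracked, and
# fitted on raw and renormalized time. Built once per run.
collapse_experiment <- function(seed = 101) fixture("collapse_e2e", function() {
  p <- synthetic_params(D_rna = 10, kappa = 0.01, psf_sigma_um = 0.15,
                        rng_seed = seed,
                        photon_scale = photon_scale_for_snr(10))
  sc <- make_scene(5, field_size_um = 28, params = p, seed = seed,
                   radii = c(4, 3, 2, 1.5, 1), n_frames = 80, z_step_um = 0.5)
  r <- render_scene(sc)
  tracks <- track_droplets(r$stack)
  list(scene = sc,
       tracks = tracks,
       fits_raw = fit_decays(tracks, renormalize = FALSE),
       fits_renorm = fit_decays(tracks, renormalize = TRUE))
})
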