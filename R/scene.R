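# Synthetic scenes: droplet placement, rendering, FRAP bleaches, puncta.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a synthetic droplet scene
#'
#' Places `n_droplets` non-overlapping spheres in a square XY field by
#' rejection sampling. Droplets rest near the lower z boundary (center height
#' equals the radius plus one z step), as sedimented condensates on a
#' coverslip do, so each droplet's midplane sits at a radius-dependent z.
#'
#' @param n_droplets Number of droplets (0 allowed).
#' @param radius_range_um Length-2 range from which radii are drawn
#'   uniformly, or ignored when `radii` is given.
#' @param field_size_um Side of the square XY field, um.
#' @param params A [synthetic_params()].
#' @param seed Integer seed; identical seeds give identical scenes.
#' @param radii Optional explicit radii (um), one per droplet.
#' @param n_frames Number of time points.
#' @param frame_interval_min Minutes between frames (default 5).
#' @param pixel_size_um Pixel size of the rendered stack (default 0.14).
#' @param z_step_um Z spacing of the rendered stack (default 0.5).
#' @param t0_offset_min Minutes between system initialization and the first
#'   frame (default 8: mixing, incubation and mounting time).
#' @param margin_um Minimum clearance between droplet surfaces and to the
#'   field edge.
#' @param max_retries Placement attempts per droplet before giving up.
#'
#' @return An object of class `synthetic_scene`: droplet table
#'   (`id, x_um, y_um, z_um, R_um`), frame times (absolute minutes since
#'   initialization), grid geometry, `params`, and empty `frap_events` /
#'   `puncta` slots (see [frap_event()] and [punctum()]).
#' @export
make_scene <- function(n_droplets,
                       radius_range_um = c(1, 4),
                       field_size_um = 30,
                       params = synthetic_params(),
                       seed = params$rng_seed,
                       radii = NULL,
                       n_frames = 40,
                       frame_interval_min = 5,
                       pixel_size_um = 0.14,
                       z_step_um = 0.5,
                       t0_offset_min = 8,
                       margin_um = 0.5,
                       max_retries = 2000) {
  stopifnot(inherits(params, "synthetic_params"), n_droplets >= 0,
            field_size_um > 0, n_frames >= 1)
  if (is.null(radii)) {
    stopifnot(length(radius_range_um) == 2L, all(radius_range_um > 0))
    if (n_droplets > 0 &&
        2 * max(radius_range_um) + 2 * margin_um > field_size_um)
      stop("radius range does not fit in the field", call. = FALSE)
  } else {
    stopifnot(length(radii) == n_droplets, all(radii > 0))
  }

  droplets <- with_seed(seed, {
    xs <- ys <- zs <- Rs <- numeric(0)
    for (i in seq_len(n_droplets)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        R <- if (is.null(radii)) stats::runif(1, radius_range_um[1], radius_range_um[2])
             else radii[i]
        lo <- R + margin_um; hi <- field_size_um - R - margin_um
        if (hi <= lo) next
        x <- stats::runif(1, lo, hi); y <- stats::runif(1, lo, hi)
        z <- R + z_step_um
        ok <- TRUE
        if (length(xs) > 0) {
          d <- sqrt((xs - x)^2 + (ys - y)^2 + (zs - z)^2)
          ok <- all(d > Rs + R + margin_um)
        }
        if (ok) {
          xs <- c(xs, x); ys <- c(ys, y); zs <- c(zs, z); Rs <- c(Rs, R)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place droplet ", i, " after ", max_retries,
             " attempts; enlarge the field or reduce n/radii", call. = FALSE)
    }
    tibble::tibble(id = seq_len(n_droplets),
                   x_um = xs, y_um = ys, z_um = zs, R_um = Rs)
  })

  z_extent <- if (n_droplets > 0) 2 * max(droplets$R_um) + 2 * z_step_um
              else 4 * z_step_um
  structure(
    list(
      droplets = droplets,
      params = params,
      times = t0_offset_min + (seq_len(n_frames) - 1) * frame_interval_min,
      field_size_um = field_size_um,
      pixel_size_um = pixel_size_um,
      z_step_um = z_step_um,
      n_z = max(2L, as.integer(ceiling(z_extent / z_step_um)) + 1L),
      frame_interval_min = frame_interval_min,
      t0_offset_min = t0_offset_min,
      seed = seed,
      frap_events = NULL,
      puncta = NULL
    ),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("<synthetic_scene>", nrow(x$droplets), "droplet(s),",
      length(x$times), "frame(s),", x$field_size_um, "um field\n")
  if (nrow(x$droplets) > 0)
    cat("  radii:", paste(signif(x$droplets$R_um, 3), collapse = ", "), "um\n")
  if (!is.null(x$frap_events)) cat("  ", nrow(x$frap_events), "FRAP event(s)\n")
  if (!is.null(x$puncta)) cat("  ", nrow(x$puncta), "punctum/a\n")
  invisible(x)
}

#' Describe a FRAP bleach event in a scene
#'
#' @param frame Bleach frame index (1-based).
#' @param droplet_id Id of the bleached droplet.
#' @param x_um,y_um Spot center (um); defaults to the droplet center.
#' @param sigma_um Gaussian bleach-spot standard deviation (um).
#' @param depth Fractional intensity destroyed at the spot center, in (0, 1].
#' @param channel Channel the bleach acts on (default "RNA").
#' @return A one-row tibble suitable for a scene's `frap_events` table.
#' @export
frap_event <- function(frame, droplet_id, x_um = NA, y_um = NA,
                       sigma_um = 0.21, depth = 0.8, channel = "RNA") {
  stopifnot(depth > 0, depth <= 1, sigma_um > 0)
  tibble::tibble(frame = as.integer(frame), droplet_id = as.integer(droplet_id),
                 x_um = x_um, y_um = y_um, sigma_um = sigma_um,
                 depth = depth, channel = channel)
}

#' Describe a bright RNA punctum that locally depletes protein
#'
#' @param droplet_id Droplet the punctum lives in.
#' @param onset_frame First frame (1-based) at which the punctum is present.
#' @param x_um,y_um,z_um Punctum center (um); defaults to the droplet center.
#' @param amplitude Peak RNA intensity added, in the units of the stack it is
#'   injected into (concentration units when rendered through a scene).
#' @param sigma_um Gaussian footprint standard deviation (um).
#' @param protein_depletion Fraction of protein signal removed at the punctum
#'   center, in [0, 1].
#' @return A one-row tibble for a scene's `puncta` table.
#' @export
punctum <- function(droplet_id, onset_frame, x_um = NA, y_um = NA, z_um = NA,
                    amplitude = 1, sigma_um = 0.3, protein_depletion = 0.5) {
  stopifnot(protein_depletion >= 0, protein_depletion <= 1, sigma_um > 0,
            amplitude >= 0)
  tibble::tibble(droplet_id = as.integer(droplet_id),
                 onset_frame = as.integer(onset_frame),
                 x_um = x_um, y_um = y_um, z_um = z_um,
                 amplitude = amplitude, sigma_um = sigma_um,
                 protein_depletion = protein_depletion)
}

scene_fill_positions <- function(scene, tab) {
  # default event/punctum positions to their droplet's center
  for (i in seq_len(nrow(tab))) {
    d <- scene$droplets[scene$droplets$id == tab$droplet_id[i], ]
    if (nrow(d) != 1) stop("unknown droplet_id ", tab$droplet_id[i], call. = FALSE)
    if (is.na(tab$x_um[i])) tab$x_um[i] <- d$x_um
    if (is.na(tab$y_um[i])) tab$y_um[i] <- d$y_um
    if ("z_um" %in% names(tab) && is.na(tab$z_um[i])) tab$z_um[i] <- d$z_um
    r2 <- (tab$x_um[i] - d$x_um)^2 + (tab$y_um[i] - d$y_um)^2
    if ("z_um" %in% names(tab)) r2 <- r2 + (tab$z_um[i] - d$z_um)^2
    if (r2 >= d$R_um^2)
      stop("event/punctum position lies outside droplet ", d$id, call. = FALSE)
  }
  tab
}

#' Photon gain needed to reach a target in-droplet signal-to-noise ratio
#'
#' SNR is defined as the in-droplet photon signal over the total noise
#' standard deviation at that intensity:
#' `SNR = ps*C0 / sqrt(ps*(C0 + background) + read_noise_sd^2)`.
#'
#' @param snr Target SNR.
#' @param C0 In-droplet concentration (a.u.).
#' @param background Background concentration (a.u.).
#' @param read_noise_sd Read noise (counts).
#' @return The photon gain `ps` achieving the target.
#' @export
photon_scale_for_snr <- function(snr, C0 = 1, background = 0.05,
                                 read_noise_sd = 2) {
  s2 <- snr^2
  (s2 * (C0 + background) +
     sqrt(s2^2 * (C0 + background)^2 + 4 * C0^2 * s2 * read_noise_sd^2)) /
    (2 * C0^2)
}

gaussian_blur_slice <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  EBImage::gblur(m, sigma = sigma_px, boundary = "replicate")
}

#' Render a synthetic scene to a calibrated image stack
#'
#' The RNA channel of each droplet follows its radial diffusion/surface
#' departure solution: a confocal section at height z reports the local
#' concentration `C(rho, t)` at 3-D radius rho. The protein channel is
#' uniform inside each droplet and scales as
#' `protein_level * (1 + protein_accum_rate * t)`. Rendering order:
#' geometric signal, FRAP bleach fields, puncta, Gaussian PSF blur,
#' `Poisson(photon_scale * (signal + background))` photon noise plus
#' additive Gaussian read noise (negative values clipped at zero).
#'
#' @param scene A [make_scene()] scene (with optional `frap_events` and
#'   `puncta` tables attached).
#' @param noise If `FALSE`, skip the Poisson/read-noise step and return the
#'   expected intensity `photon_scale * (signal + background)`.
#' @param n_r Radial cells per droplet passed to [solve_radial_departure()].
#'
#' @return A list with `stack` (an [image_stack()] with channels
#'   `c("RNA", "protein")`), `truth` (tibble: per droplet and frame the true
#'   center concentration, protein level, position and radius) and
#'   `solutions` (per-droplet `radial_solution`s).
#' @export
render_scene <- function(scene, noise = TRUE, n_r = 200L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  p <- scene$params
  px <- scene$pixel_size_um
  n_xy <- as.integer(round(scene$field_size_um / px))
  n_z <- scene$n_z
  n_t <- length(scene$times)
  xs <- (seq_len(n_xy) - 1) * px   # pixel-center coordinates
  zs <- (seq_len(n_z) - 1) * scene$z_step_um

  # per-droplet transport solutions on absolute time (0 = initialization)
  sol_times <- c(0, scene$times)
  solutions <- lapply(seq_len(nrow(scene$droplets)), function(i) {
    solve_radial_departure(scene$droplets$R_um[i], p, sol_times, n_r = n_r)
  })

  signal <- array(0, dim = c(n_t, n_z, 2L, n_xy, n_xy))
  truth <- vector("list", nrow(scene$droplets))
  for (i in seq_len(nrow(scene$droplets))) {
    d <- scene$droplets[i, ]
    sol <- solutions[[i]]
    ix <- which(abs(xs - d$x_um) <= d$R_um)
    iy <- which(abs(xs - d$y_um) <= d$R_um)
    dx2 <- (xs[ix] - d$x_um)^2
    dy2 <- (xs[iy] - d$y_um)^2
    rho_xy2 <- outer(dy2, dx2, "+")      # [y, x] block
    for (t in seq_len(n_t)) {
      tix <- t + 1L                      # row in sol (first row is t = 0)
      prot <- p$protein_level * (1 + p$protein_accum_rate * scene$times[t])
      for (z in seq_len(n_z)) {
        dz2 <- (zs[z] - d$z_um)^2
        if (dz2 >= d$R_um^2) next
        rho <- sqrt(rho_xy2 + dz2)
        inside <- rho <= d$R_um
        if (!any(inside)) next
        vals <- radial_concentration(sol, rho[inside], tix)
        blk <- matrix(signal[t, z, 1L, iy, ix], length(iy), length(ix))
        blk[inside] <- blk[inside] + vals
        signal[t, z, 1L, iy, ix] <- blk
        blkp <- matrix(signal[t, z, 2L, iy, ix], length(iy), length(ix))
        blkp[inside] <- blkp[inside] + prot
        signal[t, z, 2L, iy, ix] <- blkp
      }
    }
    truth[[i]] <- tibble::tibble(
      droplet_id = d$id, frame = seq_len(n_t), time_min = scene$times,
      x_um = d$x_um, y_um = d$y_um, z_um = d$z_um, R_um = d$R_um,
      center_conc = sol$C[-1L, 1L],
      protein_value = p$protein_level * (1 + p$protein_accum_rate * scene$times),
      total_mass = sol$total_mass[-1L]
    )
  }

  sig_stack <- image_stack(signal,
                           pixel_size_um = px,
                           frame_interval_min = scene$frame_interval_min,
                           z_step_um = scene$z_step_um,
                           channel_names = c("RNA", "protein"),
                           t0_offset_min = scene$t0_offset_min)
  rm(signal)

  if (!is.null(scene$frap_events) && nrow(scene$frap_events) > 0) {
    ev <- scene_fill_positions(scene, scene$frap_events)
    for (k in seq_len(nrow(ev)))
      sig_stack <- apply_frap_event(sig_stack, scene, ev[k, ])
  }
  if (!is.null(scene$puncta) && nrow(scene$puncta) > 0)
    sig_stack <- inject_puncta(sig_stack, scene)

  # blur and noise slice-wise: keeps peak memory to one full-size array
  sigma_px <- p$psf_sigma_um / px
  render_one <- function(sl) {
    if (sigma_px > 0) sl <- gaussian_blur_slice(sl, sigma_px)
    lam <- p$photon_scale * (sl + p$background)
    if (!noise) return(lam)
    v <- stats::rpois(length(lam), lambda = lam) +
      stats::rnorm(length(lam), 0, p$read_noise_sd)
    matrix(pmax(v, 0), n_xy, n_xy)
  }
  with_seed(if (noise) p$rng_seed else NULL, {
    for (t in seq_len(n_t)) for (z in seq_len(n_z)) for (ch in 1:2) {
      sig_stack$data[t, z, ch, , ] <- render_one(
        matrix(sig_stack$data[t, z, ch, , ], n_xy, n_xy))
    }
  })

  stack <- sig_stack
  list(stack = stack,
       truth = if (length(truth) > 0) dplyr::bind_rows(truth) else
         tibble::tibble(),
       solutions = solutions)
}

#' Apply a FRAP bleach event to a stack
#'
#' At the bleach frame the target channel is multiplied, within the bleached
#' droplet, by `1 - depth * exp(-r^2 / (2 sigma^2))`. From then on the bleach
#' field relaxes by 2-D diffusion with coefficient `D_rna` inside the
#' droplet's midplane disk (no-flux at the droplet boundary, explicit scheme
#' with a stability-bounded substep), and each later frame is multiplied by
#' the relaxed field. The same in-plane field is applied to every z slice of
#' the droplet. Because the masked no-flux update conserves the field's sum,
#' bleaching destroys intensity only at the bleach frame.
#'
#' @param stack An [image_stack()] (typically a noiseless render).
#' @param scene The [make_scene()] scene providing droplet geometry and
#'   `D_rna`.
#' @param event A one-row [frap_event()] tibble.
#' @return The modified stack.
#' @export
apply_frap_event <- function(stack, scene, event) {
  stopifnot(inherits(stack, "image_stack"), inherits(scene, "synthetic_scene"))
  event <- scene_fill_positions(scene, event)
  d <- scene$droplets[scene$droplets$id == event$droplet_id, ]
  ch <- channel_index(stack, event$channel)
  px <- stack$pixel_size_um
  n_t <- dim(stack$data)[1]; n_z <- dim(stack$data)[2]
  n_y <- dim(stack$data)[4]; n_x <- dim(stack$data)[5]
  if (event$frame < 1 || event$frame > n_t)
    stop("bleach frame outside stack", call. = FALSE)

  xs <- (seq_len(n_x) - 1) * px
  ix <- which(abs(xs - d$x_um) <= d$R_um + px)
  iy <- which(abs((seq_len(n_y) - 1) * px - d$y_um) <= d$R_um + px)
  dx <- xs[ix] - d$x_um
  dy <- (iy - 1) * px - d$y_um
  r2 <- outer(dy^2, dx^2, "+")
  mask <- r2 <= d$R_um^2
  if (!any(mask)) stop("bleach spot outside all droplets", call. = FALSE)

  sx2 <- (event$x_um - d$x_um - dx)^2
  sy2 <- (event$y_um - d$y_um - dy)^2
  g <- exp(-outer(sy2, sx2, "+") / (2 * event$sigma_um^2))
  b <- matrix(1, nrow(mask), ncol(mask))
  b[mask] <- 1 - event$depth * g[mask]

  D <- scene$params$D_rna
  dt_frame <- stack$frame_interval_min
  n_sub <- if (D > 0) max(1L, ceiling(D * dt_frame / (0.2 * px^2))) else 1L
  dt <- dt_frame / n_sub
  lam <- D * dt / px^2
  mnum <- mask * 1

  step_field <- function(b) {
    # masked no-flux 5-point Laplacian; out-of-mask neighbors contribute 0
    bm <- b * mnum
    up    <- rbind(bm[-1, , drop = FALSE], 0)
    down  <- rbind(0, bm[-nrow(b), , drop = FALSE])
    left  <- cbind(bm[, -1, drop = FALSE], 0)
    right <- cbind(0, bm[, -ncol(b), drop = FALSE])
    nup    <- rbind(mnum[-1, , drop = FALSE], 0)
    ndown  <- rbind(0, mnum[-nrow(b), , drop = FALSE])
    nleft  <- cbind(mnum[, -1, drop = FALSE], 0)
    nright <- cbind(0, mnum[, -ncol(b), drop = FALSE])
    nb <- nup + ndown + nleft + nright
    bn <- b + lam * ((up + down + left + right) - nb * b)
    bn[!mask] <- b[!mask]
    bn
  }

  apply_field <- function(t, b) {
    for (z in seq_len(n_z)) {
      blk <- matrix(stack$data[t, z, ch, iy, ix], length(iy), length(ix))
      blk[mask] <- blk[mask] * b[mask]
      stack$data[t, z, ch, iy, ix] <<- blk
    }
  }

  apply_field(event$frame, b)
  if (event$frame < n_t) {
    for (t in (event$frame + 1L):n_t) {
      for (s in seq_len(n_sub)) b <- step_field(b)
      apply_field(t, b)
    }
  }
  stack
}

#' Inject bright RNA puncta with local protein depletion
#'
#' From each punctum's onset frame onward, a 3-D Gaussian of the given
#' amplitude is added to the RNA channel and the protein channel is
#' multiplied by `1 - protein_depletion * exp(-r^2/(2 sigma^2))` over the
#' same footprint, restricted to the interior of the punctum's droplet.
#'
#' @param stack An [image_stack()] with channels "RNA" and "protein".
#' @param scene A scene whose `puncta` slot holds [punctum()] rows.
#' @return The modified stack.
#' @export
inject_puncta <- function(stack, scene) {
  stopifnot(inherits(stack, "image_stack"), inherits(scene, "synthetic_scene"))
  if (is.null(scene$puncta) || nrow(scene$puncta) == 0) return(stack)
  pu <- scene_fill_positions(scene, scene$puncta)
  ch_rna <- channel_index(stack, "RNA")
  ch_pro <- channel_index(stack, "protein")
  px <- stack$pixel_size_um
  n_t <- dim(stack$data)[1]; n_z <- dim(stack$data)[2]
  n_y <- dim(stack$data)[4]; n_x <- dim(stack$data)[5]
  xs <- (seq_len(n_x) - 1) * px
  ys <- (seq_len(n_y) - 1) * px
  zs <- (seq_len(n_z) - 1) * stack$z_step_um

  for (k in seq_len(nrow(pu))) {
    e <- pu[k, ]
    d <- scene$droplets[scene$droplets$id == e$droplet_id, ]
    ext <- 4 * e$sigma_um
    ix <- which(abs(xs - e$x_um) <= ext)
    iy <- which(abs(ys - e$y_um) <= ext)
    dx2 <- (xs[ix] - e$x_um)^2
    dy2 <- (ys[iy] - e$y_um)^2
    ddx2 <- (xs[ix] - d$x_um)^2
    ddy2 <- (ys[iy] - d$y_um)^2
    for (z in seq_len(n_z)) {
      dz2 <- (zs[z] - e$z_um)^2
      if (dz2 > ext^2) next
      g <- exp(-(outer(dy2, dx2, "+") + dz2) / (2 * e$sigma_um^2))
      inside <- (outer(ddy2, ddx2, "+") + (zs[z] - d$z_um)^2) <= d$R_um^2
      g[!inside] <- 0
      if (!any(g > 0)) next
      for (t in seq(e$onset_frame, n_t)) {
        rna <- matrix(stack$data[t, z, ch_rna, iy, ix], length(iy), length(ix))
        stack$data[t, z, ch_rna, iy, ix] <- rna + e$amplitude * g
        pro <- matrix(stack$data[t, z, ch_pro, iy, ix], length(iy), length(ix))
        stack$data[t, z, ch_pro, iy, ix] <- pro * (1 - e$protein_depletion * g)
      }
    }
  }
  stack
}
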