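# FRAP: bleach-spot location, in-droplet reference ratios, the modified
# affine normalization, per-field averaging, recovery fitting, aging series.

disk_mask <- function(ny, nx, center_yx, radius_px) {
  dy <- seq_len(ny) - center_yx[1]
  dx <- seq_len(nx) - center_yx[2]
  outer(dy^2, dx^2, "+") <= radius_px^2
}

#' Locate a FRAP bleach spot within a droplet
#'
#' Forms the difference of the Gaussian-smoothed (sigma 1 px) slices just
#' after and just before the bleach frame and takes its minimum inside the
#' droplet mask (restricted to a 5 px neighbourhood of `nominal_center_px`
#' when given). The depression must exceed 3x the robust noise level (MAD)
#' of the difference image inside the droplet, otherwise no bleach is
#' declared.
#'
#' @param stack An [image_stack()].
#' @param droplet_mask Logical Y x X midplane mask of the bleached droplet.
#' @param z Z index of the midplane.
#' @param bleach_frame Frame index of the bleach (first bleached frame).
#' @param channel Bleached channel (default "RNA").
#' @param nominal_center_px Optional `(y, x)` pixel location to search near.
#' @param spot_radius_px Spot disk radius, px (default 1.5: 3 px diameter).
#' @return List with `center_px` (y, x), `spot_mask` (Y x X logical), and
#'   `depth` (depression in intensity units).
#' @export
locate_bleach_spot <- function(stack, droplet_mask, z, bleach_frame,
                               channel = "RNA", nominal_center_px = NULL,
                               spot_radius_px = analysis_config()$frap_spot_radius_px) {
  n_t <- dim(stack$data)[1]
  if (bleach_frame < 2 || bleach_frame > n_t)
    stop("need frames on both sides of the bleach frame", call. = FALSE)
  pre <- gaussian_blur_slice(get_slice(stack, bleach_frame - 1L, z, channel), 1)
  post <- gaussian_blur_slice(get_slice(stack, bleach_frame, z, channel), 1)
  diffim <- post - pre
  search <- droplet_mask
  if (!is.null(nominal_center_px)) {
    search <- droplet_mask &
      disk_mask(nrow(diffim), ncol(diffim), nominal_center_px, 5)
  }
  if (!any(search)) stop("empty search region", call. = FALSE)
  vals <- diffim[search]
  noise <- stats::mad(diffim[droplet_mask])
  depth <- -min(vals)
  # noise floor for noiseless data: demand a depression of at least 1e-6
  # of the droplet's pre-bleach level
  floor_ <- max(3 * noise, 1e-6 * mean(pre[droplet_mask]))
  if (!is.finite(depth) || depth < floor_)
    stop("no bleach detected: depression ", signif(depth, 3),
         " below threshold ", signif(floor_, 3), call. = FALSE)
  idx <- which(search, arr.ind = TRUE)
  ctr <- idx[which.min(vals), ]
  list(center_px = c(y = unname(ctr[1]), x = unname(ctr[2])),
       spot_mask = disk_mask(nrow(diffim), ncol(diffim), ctr, spot_radius_px),
       depth = depth)
}

#' In-droplet reference intensity-ratio series
#'
#' Per frame, the ratio of the mean intensity inside the bleach spot to the
#' mean over the droplet excluding a 2 px dilation of the spot (the
#' dilation keeps bleach bleed-over out of the reference). Because both
#' numerator and denominator sit in the same droplet, global intensity
#' drift and acquisition photobleaching cancel.
#'
#' @param stack An [image_stack()].
#' @param spot_mask Logical Y x X spot mask.
#' @param droplet_mask Logical Y x X droplet midplane mask containing it.
#' @param z Midplane z index.
#' @param channel Measured channel (default "RNA").
#' @return A tibble: `frame`, `time_min` (absolute), `ratio`.
#' @export
intensity_ratio_series <- function(stack, spot_mask, droplet_mask, z,
                                   channel = "RNA") {
  if (!any(spot_mask) || !all(droplet_mask[spot_mask]))
    stop("spot mask must lie inside the droplet mask", call. = FALSE)
  grown <- EBImage::dilate(spot_mask * 1,
                           EBImage::makeBrush(5, shape = "disc")) > 0
  ref <- droplet_mask & !grown
  if (!any(ref))
    stop("empty reference region: droplet barely larger than spot",
         call. = FALSE)
  n_t <- dim(stack$data)[1]
  ratio <- vapply(seq_len(n_t), function(f) {
    sl <- get_slice(stack, f, z, channel)
    mean(sl[spot_mask]) / mean(sl[ref])
  }, numeric(1))
  tibble::tibble(frame = seq_len(n_t), time_min = frame_times(stack),
                 ratio = ratio)
}

#' Normalize a FRAP ratio series to a recovery curve
#'
#' Applies the affine rescaling `N(t) = (I(t) - I(0)) / (I_i - I(0))`, where
#' `I(0)` is the intensity ratio at the first bleached frame and `I_i` the
#' mean ratio over all pre-bleach frames. This differs from the common
#' normalization to absolute pre-bleach intensity: because `I` is already an
#' in-droplet ratio, `N` is immune to global intensity changes, starts at 0
#' exactly, and reaches 1 on full recovery to the pre-bleach ratio.
#'
#' @param ratios Output of [intensity_ratio_series()].
#' @param bleach_frame Index of the first bleached frame.
#' @param experiment_time_min Time (min after system initialization) at
#'   which this FRAP experiment was performed; defaults to the bleach
#'   frame's absolute time.
#' @return An object of class `frap_record`: `time` (min since bleach),
#'   `N`, `I_i`, `I0`, `ratio`, `bleach_frame`, `experiment_time_min`.
#' @export
normalize_frap <- function(ratios, bleach_frame, experiment_time_min = NULL) {
  stopifnot(bleach_frame >= 2, bleach_frame <= nrow(ratios))
  I_i <- mean(ratios$ratio[ratios$frame < bleach_frame])
  I0 <- ratios$ratio[ratios$frame == bleach_frame]
  if (!is.finite(I_i) || !is.finite(I0) || I_i <= I0)
    stop("invalid bleach: pre-bleach ratio I_i = ", signif(I_i, 4),
         " must exceed I(0) = ", signif(I0, 4), call. = FALSE)
  post <- ratios[ratios$frame >= bleach_frame, ]
  if (is.null(experiment_time_min))
    experiment_time_min <- post$time_min[1]
  structure(
    list(time = post$time_min - post$time_min[1],
         N = (post$ratio - I0) / (I_i - I0),
         ratio = post$ratio, I_i = I_i, I0 = I0,
         bleach_frame = bleach_frame,
         experiment_time_min = experiment_time_min),
    class = "frap_record"
  )
}

#' @export
print.frap_record <- function(x, ...) {
  cat("<frap_record>", length(x$time), "post-bleach points | I_i =",
      signif(x$I_i, 4), "I(0) =", signif(x$I0, 4), "| t_exp =",
      x$experiment_time_min, "min\n")
  invisible(x)
}

#' Average normalized FRAP curves across a field of view
#'
#' @param records List of [normalize_frap()] records sharing one time base.
#' @return A tibble: `time` (min since bleach), `mean`, `sd` (sample
#'   standard deviation across droplets; `NA` for a single record), `n`.
#' @export
average_field_of_view <- function(records) {
  stopifnot(length(records) >= 1,
            all(vapply(records, inherits, logical(1), "frap_record")))
  t0 <- records[[1]]$time
  same <- vapply(records, function(r)
    length(r$time) == length(t0) && all(abs(r$time - t0) < 1e-9), logical(1))
  if (!all(same)) stop("records have mismatched time bases", call. = FALSE)
  mat <- vapply(records, `[[`, numeric(length(t0)), "N")
  mat <- matrix(mat, nrow = length(t0))
  tibble::tibble(
    time = t0,
    mean = rowMeans(mat),
    sd = if (ncol(mat) > 1) apply(mat, 1, stats::sd) else NA_real_,
    n = ncol(mat)
  )
}

#' Fit a single-exponential FRAP recovery
#'
#' Fits `N(t) = M * (1 - exp(-t / tau_rec))` to an averaged normalized
#' recovery curve. `M` plays the role of a mobile-fraction proxy and is
#' bounded to [0, 1.2]; `tau_rec` is the recovery timescale in the curve's
#' time units (minutes).
#'
#' @param curve A tibble with `time` and `mean` (or `N`) columns, e.g. from
#'   [average_field_of_view()], at least 5 points.
#' @param experiment_time_min Optional experiment-onset time carried into
#'   aging tables.
#' @return An object of class `recovery_fit`: `M`, `tau_rec`, `rms`,
#'   `converged`, `flagged` (amplitude ~ 0, timescale unidentifiable),
#'   `n_points`, `n_droplets`, `experiment_time_min`, and the fitted curve.
#' @export
fit_recovery <- function(curve, experiment_time_min = NA_real_) {
  v <- if ("mean" %in% names(curve)) curve$mean else curve$N
  t <- curve$time
  stopifnot(length(t) == length(v))
  if (length(v) < 5L) stop("need at least 5 post-bleach points", call. = FALSE)
  M0 <- min(max(mean(v[t >= stats::quantile(t, 0.7)]), 0.1), 1.2)
  # half-time-based timescale guess, with coarser fallbacks
  i_half <- which(v >= M0 / 2)[1]
  tau_starts <- c(if (!is.na(i_half) && t[i_half] > 0) t[i_half] / log(2),
                  diff(range(t)) / 4, diff(range(t)) / 20)
  fit <- NULL
  for (tau0 in tau_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ M * (1 - exp(-t / tau)),
                        start = list(M = M0, tau = tau0),
                        lower = c(M = 0, tau = 1e-9),
                        upper = c(M = 1.2, tau = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    est <- c(M = NA_real_, tau = NA_real_)
    conv <- FALSE; flagged <- TRUE; rms <- stats::sd(v)
  } else {
    est <- stats::coef(fit)
    conv <- fit$convInfo$isConv %||% TRUE
    flagged <- unname(est["M"]) < 1e-3   # flat curve: tau unidentifiable
    rms <- sqrt(mean(stats::residuals(fit)^2))
  }
  n_d <- if ("n" %in% names(curve)) max(curve$n) else NA_integer_
  structure(
    list(M = unname(est["M"]), tau_rec = unname(est["tau"]),
         rms = rms, converged = conv, flagged = flagged,
         n_points = length(v), n_droplets = n_d,
         experiment_time_min = experiment_time_min,
         time = t, value = v),
    class = "recovery_fit"
  )
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat("<recovery_fit> M =", signif(x$M, 4), " tau_rec =",
      signif(x$tau_rec, 4), "min", if (x$flagged) "[flagged]" else "", "\n")
  invisible(x)
}

#' Assemble a FRAP aging series
#'
#' Orders recovery fits by the time at which each FRAP experiment was
#' performed after system initialization. A growing `tau_rec` along this
#' series is the signature of condensate aging: internal RNA mobility
#' slowing as the condensate matures. No smoothing is applied.
#'
#' @param fits List of [fit_recovery()] results.
#' @param experiment_times_min Optional times overriding each fit's
#'   `experiment_time_min`.
#' @return A tibble sorted by experiment time: `experiment_time_min,
#'   tau_rec_min, M, n_droplets, flagged`.
#' @export
aging_series <- function(fits, experiment_times_min = NULL) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "recovery_fit")))
  tt <- if (is.null(experiment_times_min))
    vapply(fits, `[[`, numeric(1), "experiment_time_min")
  else experiment_times_min
  out <- tibble::tibble(
    experiment_time_min = tt,
    tau_rec_min = vapply(fits, `[[`, numeric(1), "tau_rec"),
    M = vapply(fits, `[[`, numeric(1), "M"),
    n_droplets = vapply(fits, function(f) as.integer(f$n_droplets), integer(1)),
    flagged = vapply(fits, `[[`, logical(1), "flagged")
  )
  dplyr::arrange(out, .data$experiment_time_min)
}

#' Measure one FRAP event end-to-end on a stack
#'
#' Segments the pre-bleach frame, picks the droplet containing (or nearest)
#' the nominal spot, locates the bleach spot on the droplet midplane, builds
#' the in-droplet ratio series and normalizes it.
#'
#' @param stack An [image_stack()] containing a bleach.
#' @param bleach_frame First bleached frame.
#' @param nominal_center_px Optional `(y, x)` pixel hint for the spot.
#' @param seg_channel Channel used to segment the droplet (default
#'   "protein").
#' @param channel Bleached/measured channel (default "RNA").
#' @param config An [analysis_config()].
#' @param experiment_time_min Optional experiment-onset time for aging.
#' @return A [normalize_frap()] record.
#' @export
measure_frap_event <- function(stack, bleach_frame, nominal_center_px = NULL,
                               seg_channel = "protein", channel = "RNA",
                               config = analysis_config(),
                               experiment_time_min = NULL) {
  labels <- segment_frame(stack, bleach_frame - 1L, channel = seg_channel,
                          config = config)
  ids <- setdiff(unique(as.integer(labels)), 0L)
  if (length(ids) == 0) stop("no droplet found before the bleach", call. = FALSE)
  pick <- ids[1]
  if (length(ids) > 1) {
    if (is.null(nominal_center_px)) {
      sizes <- vapply(ids, function(i) sum(labels == i), numeric(1))
      pick <- ids[which.max(sizes)]
    } else {
      cents <- t(vapply(ids, function(i) {
        w <- which(apply(labels == i, c(2, 3), any), arr.ind = TRUE)
        c(mean(w[, 1]), mean(w[, 2]))
      }, numeric(2)))
      dd <- (cents[, 1] - nominal_center_px[1])^2 +
        (cents[, 2] - nominal_center_px[2])^2
      pick <- ids[which.min(dd)]
    }
  }
  mask3d <- labels == pick
  z <- select_midplane(mask3d)
  dmask <- matrix(mask3d[z, , ], dim(labels)[2], dim(labels)[3])
  spot <- locate_bleach_spot(stack, dmask, z, bleach_frame, channel = channel,
                             nominal_center_px = nominal_center_px,
                             spot_radius_px = config$frap_spot_radius_px)
  ratios <- intensity_ratio_series(stack, spot$spot_mask, dmask, z,
                                   channel = channel)
  normalize_frap(ratios, bleach_frame,
                 experiment_time_min = experiment_time_min)
}
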