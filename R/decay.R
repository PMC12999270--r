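# Center-intensity decay kinetics: time courses, radius renormalization,
# single-exponential fits with censoring, and collapse quality.

#' Construct an intensity time course
#'
#' @param time Times, minutes (absolute experiment time), strictly
#'   increasing.
#' @param value Intensities (a.u.), same length.
#' @param R_um Droplet radius used for time renormalization (um).
#' @param track_id Optional track identifier.
#' @param channel Optional channel name.
#' @param time_units `"min"` or `"min_per_um"` (after renormalization).
#' @return An object of class `time_course`.
#' @export
time_course <- function(time, value, R_um = NA_real_, track_id = NA,
                        channel = NA_character_, time_units = "min") {
  stopifnot(length(time) == length(value))
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 R_um = R_um, track_id = track_id, channel = channel,
                 time_units = time_units),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat("<time_course>", length(x$time), "points,", x$time_units,
      "| R =", x$R_um, "um | track", x$track_id, "\n")
  invisible(x)
}

#' Build per-track center-intensity time courses from a tracks table
#'
#' Applies the standard eligibility filters: border-touching observations
#' are dropped, and tracks whose mean circularity falls below
#' `circularity_min` are excluded entirely. The radius attached to each
#' course is the track-mean midplane radius (or the first-frame radius).
#'
#' @param tracks Output of [track_droplets()].
#' @param channel Channel whose center intensity is used (default "RNA").
#' @param config An [analysis_config()].
#' @param radius `"track_mean"` (default) or `"first"`.
#' @param min_points Tracks shorter than this are dropped (default 5).
#' @return A list of [time_course()] objects.
#' @export
time_courses_from_tracks <- function(tracks, channel = "RNA",
                                     config = analysis_config(),
                                     radius = c("track_mean", "first"),
                                     min_points = 5L) {
  radius <- match.arg(radius)
  col <- paste0("center_I_", channel)
  if (!col %in% names(tracks))
    stop("tracks table has no column ", col, call. = FALSE)
  keep <- !tracks$border
  tr <- tracks[keep, ]
  out <- list()
  for (id in sort(unique(tr$track_id))) {
    g <- tr[tr$track_id == id, ]
    g <- g[order(g$frame), ]
    if (nrow(g) < min_points) next
    if (mean(g$circularity, na.rm = TRUE) < config$circularity_min) next
    R <- if (radius == "track_mean") mean(g$radius_um) else g$radius_um[1]
    out[[length(out) + 1L]] <-
      time_course(g$time_min, g[[col]], R_um = R, track_id = id,
                  channel = channel)
  }
  out
}

#' Renormalize a time course by droplet radius
#'
#' Divides the time axis by the droplet radius, converting minutes to
#' min/um. When RNA loss is limited by flux through the droplet surface the
#' decay timescale grows linearly with radius, so renormalized decay curves
#' of droplets of different sizes collapse onto one master curve.
#'
#' @param tc A [time_course()] with a positive `R_um`.
#' @return The renormalized `time_course` (`time_units = "min_per_um"`).
#' @export
renormalize_time <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  if (!is.finite(tc$R_um) || tc$R_um <= 0)
    stop("time course has no positive radius", call. = FALSE)
  time_course(tc$time / tc$R_um, tc$value, R_um = tc$R_um,
              track_id = tc$track_id, channel = tc$channel,
              time_units = "min_per_um")
}

#' Detect the decay onset of a time course
#'
#' The onset is the index of the maximum of the 3-point moving average of
#' the values (shrinking window at the ends); ties resolve to the earliest
#' index. The decay fit uses points from the onset onward, so an initial
#' rise (e.g. signal still equilibrating) is excluded.
#'
#' @param tc A [time_course()] with at least 5 points.
#' @return Onset index (1-based).
#' @export
detect_decay_onset <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  v <- tc$value
  n <- length(v)
  if (n < 5L) stop("need at least 5 points to detect an onset", call. = FALSE)
  ma <- vapply(seq_len(n), function(i)
    mean(v[max(1L, i - 1L):min(n, i + 1L)]), numeric(1))
  which.max(ma)
}

#' Fit a single-exponential decay with plateau
#'
#' Fits `I(t) = A * exp(-t/tau) + B` by nonlinear least squares
#' (Levenberg-Marquardt) to the points from the onset onward, on the time
#' course's own (absolute) time axis. Keeping absolute time means `A` is the
#' amplitude referenced to system initialization (t = 0), which is what the
#' plateau-proximity censoring rule compares against: a curve whose first
#' observation is already near `B` relative to `A` had decayed before
#' observation began. Initial guesses: `A0 = (I(onset) - min(I))` scaled
#' back to t = 0, `B0 = min(I)`, `tau0` = half the fitted time span; bounds
#' `A >= 0`, `tau > 0`. Non-convergence or a vanishing amplitude (the curve
#' is flat, so tau is unidentifiable) is reported via flags, never an
#' exception.
#'
#' @param tc A [time_course()] (raw or renormalized time).
#' @param onset Onset index; default [detect_decay_onset()].
#' @return An object of class `decay_fit`: estimates `A`, `B`, `tau`
#'   (units `min` or `min_per_um` matching the input), `onset`, residual
#'   `rms`, `censored` and `converged` flags, covariance `vcov` of
#'   (A, B, tau), `n_points`, and the fitted data.
#' @export
fit_exponential_decay <- function(tc, onset = NULL) {
  stopifnot(inherits(tc, "time_course"))
  if (is.null(onset)) onset <- detect_decay_onset(tc)
  t <- tc$time[onset:length(tc$time)]
  v <- tc$value[onset:length(tc$value)]
  if (length(v) < 5L) stop("need at least 5 points after onset", call. = FALSE)
  span <- diff(range(t))
  B0 <- min(v)
  scale_v <- max(abs(v), 1e-12)

  fit <- NULL
  for (tau0 in c(span / 2, span / 5, span / 20)) {
    A0 <- max(v[1] - min(v), 0) * exp(min(t[1] / tau0, 5))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ A * exp(-t / tau) + B,
        start = list(A = A0, B = B0, tau = tau0),
        lower = c(A = 0, B = -Inf, tau = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }

  if (is.null(fit)) {
    est <- c(A = NA_real_, B = mean(v), tau = NA_real_)
    res <- list(converged = FALSE, censored = TRUE, vcov = NULL,
                rms = stats::sd(v))
  } else {
    est <- stats::coef(fit)
    flat <- est["A"] < 1e-6 * scale_v   # amplitude ~ 0: tau unidentifiable
    res <- list(converged = fit$convInfo$isConv %||% TRUE,
                censored = isTRUE(unname(flat)),
                vcov = decay_fit_vcov(est, t, v),
                rms = sqrt(mean(stats::residuals(fit)^2)))
  }

  tau_units <- if (identical(tc$time_units, "min_per_um")) "min_per_um" else "min"
  structure(
    list(A = unname(est["A"]), B = unname(est["B"]), tau = unname(est["tau"]),
         onset = onset, rms = res$rms, censored = res$censored,
         converged = res$converged, vcov = res$vcov,
         n_points = length(v), tau_units = tau_units,
         R_um = tc$R_um, track_id = tc$track_id, channel = tc$channel,
         time = t, value = v),
    class = "decay_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gauss-Newton covariance of (A, B, tau) from the analytic Jacobian;
# robust replacement for vcov.nls when the model object is degenerate.
decay_fit_vcov <- function(est, t, v) {
  A <- est[["A"]]; B <- est[["B"]]; tau <- est[["tau"]]
  n <- length(v)
  if (!all(is.finite(c(A, B, tau))) || n <= 3) return(NULL)
  e <- exp(-t / tau)
  J <- cbind(A = e, B = rep(1, n), tau = A * t / tau^2 * e)
  r <- v - (A * e + B)
  s2 <- sum(r^2) / (n - 3)
  vc <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (!is.null(vc)) dimnames(vc) <- list(names(est), names(est))
  vc
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> A =", signif(x$A, 4), " B =", signif(x$B, 4),
      " tau =", signif(x$tau, 4), x$tau_units,
      if (x$censored) "[censored]" else "", "\n")
  invisible(x)
}

#' Apply the fast-decay censoring rule
#'
#' A renormalized decay timescale below `censor_threshold_min_per_um`
#' (default 10 min/um) cannot be measured reliably: the fluorescence has
#' decayed to near its plateau by the observation onset. A fit is flagged
#' censored when `tau` is below the threshold, or when the first observed
#' value is already within 20% of the amplitude above the plateau
#' (`I(onset) < B + 0.2 A`). Censored timescales are upper bounds only.
#'
#' @param fit A `decay_fit` on renormalized (min/um) time.
#' @param censor_threshold_min_per_um Threshold, min/um.
#' @return The fit with its `censored` flag updated.
#' @export
censor_fast_decays <- function(fit,
                               censor_threshold_min_per_um = analysis_config()$censor_threshold_min_per_um) {
  stopifnot(inherits(fit, "decay_fit"))
  near_plateau <- is.finite(fit$A) && is.finite(fit$B) &&
    fit$value[1] < fit$B + 0.2 * fit$A
  fast <- is.finite(fit$tau) && fit$tau < censor_threshold_min_per_um
  fit$censored <- fit$censored || fast || near_plateau
  fit
}

#' Quantify decay-curve collapse under radius renormalization
#'
#' Given raw-time decay fits across droplets of different radii, computes
#' the dispersion of the renormalized timescales `tau / R` (their
#' coefficient of variation), the dispersion of the raw `tau`, and the
#' least-squares slope of `tau` versus `R` through the origin. A
#' surface-flux-limited process has `tau` proportional to `R`: low
#' `cv_renormalized`, raw `tau` spanning the radius ratio, slope
#' `1/(3 kappa)`.
#'
#' @param fits List of uncensored `decay_fit`s on raw (min) time.
#' @param radii Radii (um); defaults to each fit's `R_um`.
#' @return A one-row tibble: `n`, `cv_renormalized`, `cv_raw`,
#'   `tau_span` (max/min of raw tau), `slope_raw` (tau vs R through origin),
#'   `r_squared`.
#' @export
collapse_quality <- function(fits, radii = NULL) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, logical(1), "decay_fit")))
  keep <- !vapply(fits, `[[`, logical(1), "censored")
  fits <- fits[keep]
  if (is.null(radii)) radii <- vapply(fits, `[[`, numeric(1), "R_um")
  else radii <- radii[keep]
  if (length(fits) < 3L)
    stop("need at least 3 uncensored fits", call. = FALSE)
  if (max(radii) / min(radii) < 2)
    stop("insufficient spread in radii (need >= 2x range)", call. = FALSE)
  tau <- vapply(fits, `[[`, numeric(1), "tau")
  ratio <- tau / radii
  m <- stats::lm(tau ~ radii - 1)
  # suppressWarnings: summary() warns on noiseless, numerically perfect fits
  r2 <- suppressWarnings(summary(m)$r.squared)
  tibble::tibble(
    n = length(tau),
    cv_renormalized = stats::sd(ratio) / mean(ratio),
    cv_raw = stats::sd(tau) / mean(tau),
    tau_span = max(tau) / min(tau),
    slope_raw = unname(stats::coef(m)[1]),
    r_squared = r2
  )
}

#' Fit exponential decays for every eligible track
#'
#' Convenience wrapper: builds center-intensity time courses from a tracks
#' table, optionally renormalizes time by each track's mean radius, detects
#' onsets, fits, and applies the censoring rule (on renormalized fits).
#'
#' @param tracks Output of [track_droplets()].
#' @param channel Intensity channel (default "RNA").
#' @param config An [analysis_config()].
#' @param renormalize Fit on `t / R` (min/um) when `TRUE`.
#' @return A tibble with one row per fitted track: `track_id, R_um,
#'   n_points, onset, A, B, tau, tau_units, censored, converged, rms` and a
#'   `fit` list-column holding the `decay_fit` objects.
#' @export
fit_decays <- function(tracks, channel = "RNA", config = analysis_config(),
                       renormalize = TRUE) {
  tcs <- time_courses_from_tracks(tracks, channel = channel, config = config)
  fits <- lapply(tcs, function(tc) {
    if (renormalize) tc <- renormalize_time(tc)
    f <- fit_exponential_decay(tc)
    if (renormalize) f <- censor_fast_decays(f, config$censor_threshold_min_per_um)
    f
  })
  tibble::tibble(
    track_id = vapply(fits, function(f) as.integer(f$track_id), integer(1)),
    R_um = vapply(fits, `[[`, numeric(1), "R_um"),
    n_points = vapply(fits, `[[`, integer(1), "n_points"),
    onset = vapply(fits, `[[`, integer(1), "onset"),
    A = vapply(fits, `[[`, numeric(1), "A"),
    B = vapply(fits, `[[`, numeric(1), "B"),
    tau = vapply(fits, `[[`, numeric(1), "tau"),
    tau_units = vapply(fits, `[[`, character(1), "tau_units"),
    censored = vapply(fits, `[[`, logical(1), "censored"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    rms = vapply(fits, `[[`, numeric(1), "rms"),
    fit = fits
  )
}
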