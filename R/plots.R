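# ggplot2 figures for the main result types.

#' Plot radius-colored center-intensity decay curves
#'
#' @param tracks Output of [track_droplets()].
#' @param channel Intensity channel (default "RNA").
#' @param renormalize Plot against `t / R` (min/um) instead of minutes.
#' @param config An [analysis_config()].
#' @return A ggplot.
#' @export
plot_decay_curves <- function(tracks, channel = "RNA", renormalize = FALSE,
                              config = analysis_config()) {
  tcs <- time_courses_from_tracks(tracks, channel = channel, config = config)
  df <- dplyr::bind_rows(lapply(tcs, function(tc) {
    if (renormalize) tc <- renormalize_time(tc)
    tibble::tibble(track_id = tc$track_id, R_um = tc$R_um,
                   time = tc$time, value = tc$value)
  }))
  xlab <- if (renormalize) "time / R (min/µm)" else "time (min)"
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   group = .data$track_id,
                                   colour = .data$R_um)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_c(name = "R (µm)") +
    ggplot2::labs(x = xlab, y = paste(channel, "center intensity (a.u.)")) +
    ggplot2::theme_minimal()
}

#' Plot a decay fit over its data
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  df <- tibble::tibble(time = object$time, value = object$value)
  xlab <- if (object$tau_units == "min_per_um")
    "time / R (min/µm)" else "time (min)"
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
  if (is.finite(object$tau)) {
    tt <- seq(min(df$time), max(df$time), length.out = 200)
    fitdf <- tibble::tibble(time = tt,
                            value = object$A * exp(-tt / object$tau) + object$B)
    p <- p + ggplot2::geom_line(data = fitdf, colour = "firebrick")
  }
  p
}

#' Plot a FRAP recovery fit
#'
#' @param object A `recovery_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot recovery_fit
#' @export
autoplot.recovery_fit <- function(object, ...) {
  df <- tibble::tibble(time = object$time, value = object$value)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time since bleach (min)", y = "normalized recovery N(t)") +
    ggplot2::theme_minimal()
  if (is.finite(object$tau_rec)) {
    tt <- seq(0, max(df$time), length.out = 200)
    fitdf <- tibble::tibble(
      time = tt, value = object$M * (1 - exp(-tt / object$tau_rec)))
    p <- p + ggplot2::geom_line(data = fitdf, colour = "steelblue")
  }
  p
}

#' Plot an aging series (recovery timescale vs experiment time)
#'
#' @param aging A tibble from [aging_series()].
#' @return A ggplot.
#' @export
plot_aging <- function(aging) {
  ggplot2::ggplot(aging, ggplot2::aes(.data$experiment_time_min,
                                      .data$tau_rec_min)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "experiment time after initialization (min)",
                  y = expression(tau[rec] ~ "(min)")) +
    ggplot2::theme_minimal()
}

#' Plot a radial intensity profile
#'
#' @param profile A tibble from [radial_profile()].
#' @return A ggplot.
#' @export
plot_radial_profile <- function(profile) {
  ggplot2::ggplot(profile[profile$n_px > 0, ],
                  ggplot2::aes(.data$r_mid_um, .data$mean_intensity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "radius (µm)", y = "mean intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
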