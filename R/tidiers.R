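# broom-style tidy()/glance() methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decay fit
#'
#' @param x A `decay_fit` from [fit_exponential_decay()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`A`, `B`, `tau`):
#'   `term, estimate, std.error`.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  se <- rep(NA_real_, 3)
  if (!is.null(x$vcov)) se <- sqrt(pmax(diag(x$vcov), 0))
  tibble::tibble(term = c("A", "B", "tau"),
                 estimate = c(x$A, x$B, x$tau),
                 std.error = unname(se))
}

#' Glance at a decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `tau, tau_units, R_um, censored, converged,
#'   rms, n_points, onset`.
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(tau = x$tau, tau_units = x$tau_units, R_um = x$R_um,
                 censored = x$censored, converged = x$converged,
                 rms = x$rms, n_points = x$n_points, onset = x$onset)
}

#' Tidy a FRAP recovery fit
#'
#' @param x A `recovery_fit` from [fit_recovery()].
#' @param ... Unused.
#' @return A tibble with rows for `M` and `tau_rec`.
#' @method tidy recovery_fit
#' @export
tidy.recovery_fit <- function(x, ...) {
  tibble::tibble(term = c("M", "tau_rec"),
                 estimate = c(x$M, x$tau_rec))
}

#' Glance at a FRAP recovery fit
#'
#' @param x A `recovery_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `M, tau_rec, rms, converged, flagged,
#'   n_points, n_droplets, experiment_time_min`.
#' @method glance recovery_fit
#' @export
glance.recovery_fit <- function(x, ...) {
  tibble::tibble(M = x$M, tau_rec = x$tau_rec, rms = x$rms,
                 converged = x$converged, flagged = x$flagged,
                 n_points = x$n_points, n_droplets = x$n_droplets,
                 experiment_time_min = x$experiment_time_min)
}
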