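#' Analysis configuration
#'
#' Bundles the tunable parameters of the measurement pipeline. Defaults are
#' the pipeline's standard analysis constants: 0.24 um radial bins, a
#' circularity filter of 0.9 for radial
#' profiles and decay fits, a censoring bound of 10 min/um on
#' radius-renormalized decay timescales, and a 1.5 px FRAP spot radius
#' (3-pixel spot diameter, roughly 0.42 um at 0.14 um pixels).
#'
#' @param radial_bin_um Radial bin width for intensity profiles (um).
#' @param circularity_min Minimum midplane circularity (4*pi*A/P^2) for a
#'   droplet to enter radial profiles and decay fits.
#' @param censor_threshold_min_per_um Renormalized decay timescales below
#'   this bound (min/um) are flagged censored: the fluorescence has decayed
#'   to near its plateau by the observation onset and the fit reports only
#'   an upper bound.
#' @param max_link_displacement_um Gate for frame-to-frame centroid linking;
#'   candidate links farther than this are rejected.
#' @param min_droplet_area_px Minimum midplane area (pixels) kept by
#'   segmentation.
#' @param frap_spot_radius_px Radius of the FRAP bleach-spot disk, pixels.
#' @param rng_seed Optional integer seed threaded through stochastic steps.
#'
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(radial_bin_um = 0.24,
                            circularity_min = 0.9,
                            censor_threshold_min_per_um = 10,
                            max_link_displacement_um = 1,
                            min_droplet_area_px = 20,
                            frap_spot_radius_px = 1.5,
                            rng_seed = NULL) {
  cfg <- list(
    radial_bin_um = radial_bin_um,
    circularity_min = circularity_min,
    censor_threshold_min_per_um = censor_threshold_min_per_um,
    max_link_displacement_um = max_link_displacement_um,
    min_droplet_area_px = min_droplet_area_px,
    frap_spot_radius_px = frap_spot_radius_px,
    rng_seed = rng_seed
  )
  num <- cfg[setdiff(names(cfg), "rng_seed")]
  bad <- names(num)[!vapply(num, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad) > 0)
    stop("config thresholds must be positive numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (k in names(x)) cat("  ", k, ": ",
                          if (is.null(x[[k]])) "NULL" else x[[k]], "\n", sep = "")
  invisible(x)
}

#' Load an analysis configuration from YAML or JSON
#'
#' Absent keys fall back to the [analysis_config()] defaults. Unknown keys
#' are an error, so typos in a config file never silently revert a parameter
#' to its default.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. An empty file
#'   yields the full default configuration.
#' @return An [analysis_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must hold a mapping", call. = FALSE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; known keys: ", paste(known, collapse = ", "), call. = FALSE)
  do.call(analysis_config, vals)
}
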