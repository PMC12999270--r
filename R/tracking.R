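# Linking per-frame droplet observations into trajectories.

#' Link per-frame observations into droplet tracks
#'
#' Greedy nearest-neighbour linking on midplane centroids: for each pair of
#' consecutive frames, candidate links are sorted by centroid distance and
#' accepted in ascending order, each observation used at most once, and any
#' link longer than `max_link_displacement_um` rejected. Unmatched
#' observations start new tracks; a track with no match in the next frame
#' simply ends (no gap closing). Greedy linking is appropriate here because
#' condensates in this system are nearly stationary between frames.
#'
#' @param observations A tibble with at least `frame`, `x_um`, `y_um`
#'   (e.g. rows from [measure_observation()]).
#' @param max_link_displacement_um Link gate in um (default from
#'   [analysis_config()]: 1 um per frame).
#' @return The input tibble with a `track_id` column, ordered by
#'   `track_id`, then `frame`.
#' @export
link_tracks <- function(observations,
                        max_link_displacement_um = analysis_config()$max_link_displacement_um) {
  obs <- observations
  if (nrow(obs) == 0) {
    obs$track_id <- integer(0)
    return(obs)
  }
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(obs)))
  obs$.row <- seq_len(nrow(obs))
  obs$track_id <- NA_integer_
  frames <- sort(unique(obs$frame))
  next_id <- 0L
  prev_idx <- integer(0)
  for (f in frames) {
    cur_idx <- which(obs$frame == f)
    assigned <- rep(FALSE, length(cur_idx))
    if (length(prev_idx) > 0 && length(cur_idx) > 0) {
      dx <- outer(obs$x_um[prev_idx], obs$x_um[cur_idx], "-")
      dy <- outer(obs$y_um[prev_idx], obs$y_um[cur_idx], "-")
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= max_link_displacement_um, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        cand <- cand[order(dist[cand]), , drop = FALSE]
        used_prev <- rep(FALSE, length(prev_idx))
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (used_prev[i] || assigned[j]) next
          obs$track_id[cur_idx[j]] <- obs$track_id[prev_idx[i]]
          used_prev[i] <- TRUE
          assigned[j] <- TRUE
        }
      }
    }
    for (j in which(!assigned)) {
      next_id <- next_id + 1L
      obs$track_id[cur_idx[j]] <- next_id
    }
    prev_idx <- cur_idx
  }
  obs <- obs[order(obs$track_id, obs$frame), ]
  obs$.row <- NULL
  dplyr::relocate(obs, "track_id")
}

#' Segment, measure and track droplets through a time-lapse stack
#'
#' Runs [segment_frame()] and [measure_observation()] on every frame and
#' links the observations with [link_tracks()]. This is the tabular entry
#' point of the measurement pipeline: one row per (track, frame).
#'
#' @param stack An [image_stack()].
#' @param channel Segmentation channel (default "protein").
#' @param config An [analysis_config()].
#' @return A tibble: `track_id, frame, time_min, label, z_mid, x_um, y_um,
#'   area_px, radius_um, circularity, border`, plus `center_I_<ch>` and
#'   `mean_I_<ch>` per channel. `time_min` is absolute experiment time
#'   (`t0_offset_min + (frame - 1) * frame_interval_min`).
#' @export
track_droplets <- function(stack, channel = "protein",
                           config = analysis_config()) {
  n_t <- dim(stack$data)[1]
  times <- frame_times(stack)
  rows <- vector("list", n_t)
  for (f in seq_len(n_t)) {
    labels <- segment_frame(stack, f, channel = channel, config = config)
    ids <- setdiff(sort(unique(as.integer(labels))), 0L)
    if (length(ids) == 0) next
    rows[[f]] <- dplyr::bind_rows(
      lapply(ids, function(id) measure_observation(labels, stack, f, id))
    )
  }
  obs <- dplyr::bind_rows(rows)
  if (nrow(obs) == 0) {
    return(tibble::tibble(track_id = integer(0), frame = integer(0),
                          time_min = numeric(0)))
  }
  obs <- link_tracks(obs, config$max_link_displacement_um)
  obs$time_min <- times[obs$frame]
  dplyr::relocate(obs, "track_id", "frame", "time_min")
}

#' Per-track summary
#'
#' @param tracks Output of [track_droplets()].
#' @return One row per track: mean radius, mean circularity, birth and death
#'   frames, track length, and whether any observation touched the border.
#' @export
track_summary <- function(tracks) {
  dplyr::summarise(
    dplyr::group_by(tracks, .data$track_id),
    R_um = mean(.data$radius_um),
    circularity = mean(.data$circularity),
    birth_frame = min(.data$frame),
    death_frame = max(.data$frame),
    n_frames = dplyr::n(),
    any_border = any(.data$border),
    .groups = "drop"
  )
}

#' Write a tracks (or any result) table to CSV
#'
#' Deterministic plain CSV writer used for all result tables: same inputs
#' and seed give byte-identical files.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
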