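# Pixelwise colocalization: RNA puncta segmentation inside protein-masked
# droplets and the normalized product of differences from the mean.

#' Segment bright RNA puncta within a droplet mask
#'
#' Thresholds the RNA channel at its in-mask mean plus `k_sd` standard
#' deviations (a second segmentation inside the protein-defined droplet
#' contour) and keeps 8-connected components of at least `min_area_px`
#' pixels.
#'
#' @param rna_img Y x X RNA midplane intensity matrix.
#' @param droplet_mask Logical Y x X droplet mask (from the protein
#'   channel).
#' @param k_sd Threshold offset in standard deviations (default 2).
#' @param min_area_px Minimum punctum area (default 4 px).
#' @return Integer Y x X label matrix; 0 outside puncta. An empty result is
#'   valid (no puncta).
#' @export
segment_puncta <- function(rna_img, droplet_mask, k_sd = 2, min_area_px = 4L) {
  if (!any(droplet_mask)) stop("empty droplet mask", call. = FALSE)
  mu <- mean(rna_img[droplet_mask])
  sdv <- stats::sd(rna_img[droplet_mask])
  thr <- mu + k_sd * sdv
  m <- droplet_mask & rna_img > thr
  if (!any(m)) return(matrix(0L, nrow(rna_img), ncol(rna_img)))
  l <- label_components_8(m * 1)
  tab <- tabulate(l[l > 0L])
  keep <- which(tab >= min_area_px)
  out <- matrix(0L, nrow(rna_img), ncol(rna_img))
  if (length(keep) == 0L) return(out)
  newid <- integer(max(l))
  newid[keep] <- seq_along(keep)
  out[l > 0L] <- newid[l[l > 0L]]
  out
}

#' Pixelwise normalized product of differences from the mean
#'
#' For channels A and B over a mask, computes
#' `map(i,j) = (A_ij - mean(A)) * (B_ij - mean(B)) / (sd_A * sd_B)`,
#' with means and (population) standard deviations taken over the mask.
#' With this normalization the mean of the map over the mask equals the
#' Pearson correlation of the two channels exactly; the sign of each pixel
#' (co-variation vs mutual exclusion) is independent of the normalization
#' choice. Positive pixels mark co-enrichment, negative pixels mutual
#' exclusion of the two labels.
#'
#' @param A,B Y x X intensity matrices (channel 1 and channel 2).
#' @param mask Logical Y x X mask (the droplet contour); needs >= 2 pixels.
#' @return A Y x X numeric matrix, `NA` outside the mask.
#' @export
ncorr_map <- function(A, B, mask) {
  stopifnot(identical(dim(A), dim(B)), identical(dim(A), dim(mask)))
  n <- sum(mask)
  if (n < 2) stop("mask must contain at least 2 pixels", call. = FALSE)
  a <- A[mask]; b <- B[mask]
  sa <- sqrt(mean((a - mean(a))^2))   # population sd
  sb <- sqrt(mean((b - mean(b))^2))
  if (sa == 0 || sb == 0)
    stop("constant channel within mask: correlation undefined", call. = FALSE)
  out <- matrix(NA_real_, nrow(A), ncol(A))
  out[mask] <- (a - mean(a)) * (b - mean(b)) / (sa * sb)
  out
}

#' Summarize puncta against a colocalization map
#'
#' @param puncta_labels Integer label matrix from [segment_puncta()].
#' @param map Matrix from [ncorr_map()] on the same grid.
#' @return A tibble with one row per punctum: `punctum_id, area_px,
#'   mean_ncorr, frac_negative` (fraction of the punctum's pixels with a
#'   negative map value). Empty when there are no puncta.
#' @export
summarize_overlap <- function(puncta_labels, map) {
  stopifnot(identical(dim(puncta_labels), dim(map)))
  ids <- setdiff(sort(unique(as.integer(puncta_labels))), 0L)
  if (length(ids) == 0)
    return(tibble::tibble(punctum_id = integer(0), area_px = integer(0),
                          mean_ncorr = numeric(0), frac_negative = numeric(0)))
  dplyr::bind_rows(lapply(ids, function(i) {
    v <- map[puncta_labels == i]
    v <- v[!is.na(v)]
    tibble::tibble(punctum_id = i, area_px = length(v),
                   mean_ncorr = mean(v), frac_negative = mean(v < 0))
  }))
}

#' Droplet-level colocalization analysis of one frame
#'
#' Segments droplets on the protein channel, then per droplet midplane:
#' computes the normalized product-of-differences map between RNA and
#' protein, its mask mean (the Pearson correlation), and the per-punctum
#' overlap statistics from a second RNA segmentation inside the droplet.
#'
#' @param stack An [image_stack()] with "RNA" and "protein" channels.
#' @param frame Frame index.
#' @param config An [analysis_config()].
#' @param k_sd,min_area_px Puncta segmentation parameters
#'   (see [segment_puncta()]).
#' @return A list with `droplets` (tibble: `label, z_mid, pearson_r,
#'   n_puncta`) and `puncta` (tibble from [summarize_overlap()] with a
#'   `label` column).
#' @export
colocalize_frame <- function(stack, frame, config = analysis_config(),
                             k_sd = 2, min_area_px = 4L) {
  labels <- segment_frame(stack, frame, channel = "protein", config = config)
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  drows <- list(); prows <- list()
  for (id in ids) {
    mask3d <- labels == id
    z <- select_midplane(mask3d)
    dmask <- matrix(mask3d[z, , ], dim(labels)[2], dim(labels)[3])
    rna <- get_slice(stack, frame, z, "RNA")
    pro <- get_slice(stack, frame, z, "protein")
    map <- tryCatch(ncorr_map(rna, pro, dmask), error = function(e) NULL)
    if (is.null(map)) next
    pl <- segment_puncta(rna, dmask, k_sd = k_sd, min_area_px = min_area_px)
    ov <- summarize_overlap(pl, map)
    drows[[length(drows) + 1L]] <- tibble::tibble(
      label = id, z_mid = z, pearson_r = mean(map[dmask]),
      n_puncta = nrow(ov))
    if (nrow(ov) > 0) {
      ov$label <- id
      prows[[length(prows) + 1L]] <- ov
    }
  }
  list(droplets = dplyr::bind_rows(drows),
       puncta = dplyr::bind_rows(prows))
}
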