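# Droplet detection, midplane selection, shape/intensity measurement.

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

relabel_union <- function(labels, pairs) {
  # merge integer labels according to an n x 2 matrix of equivalent pairs
  if (max(labels) == 0L) return(labels)
  parent <- seq_len(max(labels))
  if (!is.null(pairs) && nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      a <- uf_find(parent, pairs[k, 1]); b <- uf_find(parent, pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
  compact <- match(roots, sort(unique(roots)))
  out <- labels
  nz <- labels > 0L
  out[nz] <- compact[labels[nz]]
  out
}

label_components_8 <- function(mask) {
  # 8-connected labeling: 4-connected pass, then merge diagonal neighbours
  l <- EBImage::bwlabel(mask * 1)
  storage.mode(l) <- "integer"
  if (max(l) == 0L) return(l)
  nr <- nrow(l); nc <- ncol(l)
  a <- l[-nr, -nc]; b <- l[-1, -1]     # main diagonal
  c_ <- l[-1, -nc]; d <- l[-nr, -1]    # anti-diagonal
  pr <- rbind(cbind(as.vector(a), as.vector(b)),
              cbind(as.vector(c_), as.vector(d)))
  pr <- pr[pr[, 1] > 0 & pr[, 2] > 0 & pr[, 1] != pr[, 2], , drop = FALSE]
  relabel_union(l, unique(pr))
}

#' Segment droplets in one frame of a stack
#'
#' Per frame: each z slice of the segmentation channel is smoothed with a
#' Gaussian (sigma 1 px), a single global Otsu threshold is computed over the
#' whole smoothed volume, holes are filled per slice, objects smaller than
#' `min_droplet_area_px` are removed, in-plane components are labeled with
#' 8-connectivity, and slices are stitched into 3-D droplets wherever two
#' components in adjacent z slices overlap by at least 50% of the smaller
#' one's area.
#'
#' Segmentation runs on the protein channel by default: the protein signal
#' stays spatially homogeneous inside droplets while RNA develops gradients
#' and leaves the condensed phase, so the protein contour is the stable
#' definition of the droplet.
#'
#' @param stack An [image_stack()].
#' @param frame Frame index (1-based).
#' @param channel Segmentation channel (default "protein").
#' @param config An [analysis_config()].
#' @return An integer Z x Y x X label array; 0 is background. An
#'   all-background frame yields an all-zero array.
#' @export
segment_frame <- function(stack, frame, channel = "protein",
                          config = analysis_config()) {
  vol <- get_volume(stack, frame, channel)
  n_z <- dim(vol)[1]
  sm <- vol
  for (z in seq_len(n_z))
    sm[z, , ] <- gaussian_blur_slice(matrix(vol[z, , ], dim(vol)[2], dim(vol)[3]),
                                     sigma_px = 1)
  rng <- range(sm)
  if (diff(rng) == 0) return(array(0L, dim = dim(vol)))
  thr <- EBImage::otsu(EBImage::Image(as.numeric(sm)), range = rng,
                       levels = 256L)
  labels <- array(0L, dim = dim(vol))
  offset <- 0L
  areas <- integer(0)
  for (z in seq_len(n_z)) {
    m <- matrix(sm[z, , ] > thr, dim(vol)[2], dim(vol)[3])
    if (!any(m)) next
    m <- EBImage::fillHull(m * 1) > 0
    l <- label_components_8(m)
    if (max(l) == 0L) next
    tab <- tabulate(l[l > 0L])
    keep <- which(tab >= config$min_droplet_area_px)
    if (length(keep) == 0L) next
    newid <- integer(max(l))
    newid[keep] <- offset + seq_along(keep)
    lz <- l
    lz[l > 0L] <- newid[l[l > 0L]]
    labels[z, , ] <- lz
    offset <- offset + length(keep)
    areas <- c(areas, tab[keep])
  }
  if (offset == 0L) return(labels)

  # stitch across z: link components overlapping >= 50% of the smaller
  pairs <- NULL
  for (z in seq_len(n_z - 1L)) {
    a <- labels[z, , ]; b <- labels[z + 1L, , ]
    both <- a > 0L & b > 0L
    if (!any(both)) next
    ov <- table(a[both], b[both])
    for (i in rownames(ov)) for (j in colnames(ov)) {
      n_ov <- ov[i, j]
      if (n_ov == 0) next
      ii <- as.integer(i); jj <- as.integer(j)
      if (n_ov >= 0.5 * min(areas[ii], areas[jj]))
        pairs <- rbind(pairs, c(ii, jj))
    }
  }
  relabel_union(labels, pairs)
}

#' Select a droplet's midplane
#'
#' The midplane is the z slice with the largest in-plane pixel count; ties
#' go to the lowest z.
#'
#' @param mask3d Logical (or 0/1) Z x Y x X array for one droplet.
#' @return The midplane z index (1-based).
#' @export
select_midplane <- function(mask3d) {
  stopifnot(length(dim(mask3d)) == 3L)
  counts <- apply(mask3d > 0, 1, sum)
  if (all(counts == 0)) stop("empty droplet mask", call. = FALSE)
  which.max(counts)   # which.max returns the first (lowest z) maximum
}

smooth_closed <- function(v, w) {
  n <- length(v)
  if (n <= 2 * w + 1) return(v)
  ext <- c(v[(n - w + 1):n], v, v[1:w])
  as.numeric(stats::filter(ext, rep(1 / (2 * w + 1), 2 * w + 1)))[(w + 1):(w + n)]
}

#' Perimeter of a binary region via a smoothed sub-pixel contour
#'
#' Extracts the 0.5-level marching-squares contour of the mask, applies a
#' short circular moving average to suppress pixelation staircase, and sums
#' the polygon edge lengths. A rasterized disk of radius >= 7 px measures
#' within ~1% of 2*pi*r, so ideal circular droplets score circularity near 1
#' while squares stay well below the 0.9 filter.
#'
#' @param mask Logical or 0/1 matrix.
#' @param smooth_w Half-width of the circular smoothing window (default 2).
#' @return Perimeter in pixel units.
#' @export
region_perimeter <- function(mask, smooth_w = 2L) {
  m <- mask * 1
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  cl <- grDevices::contourLines(seq_len(nr + 2L), seq_len(nc + 2L), pad,
                                levels = 0.5)
  if (length(cl) == 0) return(0)
  sum(vapply(cl, function(cc) {
    x <- cc$x; y <- cc$y
    n <- length(x)
    if (n > 1 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
    xs <- smooth_closed(x, smooth_w); ys <- smooth_closed(y, smooth_w)
    sum(sqrt(diff(c(xs, xs[1]))^2 + diff(c(ys, ys[1]))^2))
  }, numeric(1)))
}

#' Measure one droplet observation
#'
#' Computes, on the droplet's midplane: the intensity-unweighted mask
#' centroid, midplane area and equivalent-area radius
#' `sqrt(area * pixel^2 / pi)`, circularity `4*pi*A/P^2` from the smoothed
#' sub-pixel contour perimeter, the per-channel center intensity (mean over
#' the 3x3 pixel neighborhood of the pixel nearest the centroid) and the
#' per-channel in-droplet mean. A droplet whose midplane touches the image
#' border is flagged (`border = TRUE`) and should be excluded from radial
#' profiles and decay fits.
#'
#' @param labels3d Label array from [segment_frame()].
#' @param stack The source [image_stack()].
#' @param frame Frame index the labels belong to.
#' @param label_id Which label to measure.
#' @return A one-row tibble: `frame, label, z_mid, x_um, y_um, area_px,
#'   radius_um, circularity, border`, then `center_I_<ch>` and
#'   `mean_I_<ch>` per channel.
#' @export
measure_observation <- function(labels3d, stack, frame, label_id) {
  mask3d <- labels3d == label_id
  if (!any(mask3d)) stop("label ", label_id, " not present", call. = FALSE)
  z_mid <- select_midplane(mask3d)
  d <- dim(labels3d)
  m <- matrix(mask3d[z_mid, , ], d[2], d[3])
  px <- stack$pixel_size_um
  idx <- which(m, arr.ind = TRUE)      # [,1] = y (row), [,2] = x (col)
  area <- nrow(idx)
  cy_px <- mean(idx[, 1]) - 1          # 0-based pixel-center coordinates
  cx_px <- mean(idx[, 2]) - 1
  per <- region_perimeter(m)
  circ <- if (per > 0) 4 * pi * area / per^2 else NA_real_
  border <- any(idx[, 1] == 1L) || any(idx[, 1] == d[2]) ||
    any(idx[, 2] == 1L) || any(idx[, 2] == d[3])

  iy0 <- round(cy_px) + 1L; ix0 <- round(cx_px) + 1L
  ny <- dim(stack$data)[4]; nx <- dim(stack$data)[5]
  iy <- max(1L, iy0 - 1L):min(ny, iy0 + 1L)
  ix <- max(1L, ix0 - 1L):min(nx, ix0 + 1L)

  out <- tibble::tibble(
    frame = frame, label = label_id, z_mid = z_mid,
    x_um = cx_px * px, y_um = cy_px * px,
    area_px = area,
    radius_um = sqrt(area * px^2 / pi),
    circularity = circ,
    border = border
  )
  for (ch in seq_along(stack$channel_names)) {
    nm <- stack$channel_names[ch]
    ctr <- mean(stack$data[frame, z_mid, ch, iy, ix])
    sl <- matrix(stack$data[frame, z_mid, ch, , ], d[2], d[3])
    out[[paste0("center_I_", nm)]] <- ctr
    out[[paste0("mean_I_", nm)]] <- mean(sl[m])
  }
  out
}

#' Radial intensity profile around a droplet center
#'
#' Averages pixel intensities in annular bins `[k*bin, (k+1)*bin)` of
#' pixel-center distance from the centroid, out to the droplet radius.
#' Empty bins are reported with `n_px = 0` and `mean_intensity = NA`.
#'
#' @param img Y x X midplane intensity matrix.
#' @param centroid_um Length-2 `(x, y)` centroid in um (pixel-center
#'   coordinates, origin at the first pixel center).
#' @param R_um Droplet radius: profiles extend to `ceiling(R/bin)` bins.
#' @param pixel_size_um Pixel size (um).
#' @param radial_bin_um Bin width (default 0.24 um).
#' @return A tibble: `bin, r_lo_um, r_mid_um, mean_intensity, n_px`.
#' @export
radial_profile <- function(img, centroid_um, R_um, pixel_size_um,
                           radial_bin_um = 0.24) {
  ny <- nrow(img); nx <- ncol(img)
  cx <- centroid_um[1]; cy <- centroid_um[2]
  if (cx < 0 || cy < 0 || cx > (nx - 1) * pixel_size_um ||
      cy > (ny - 1) * pixel_size_um)
    stop("centroid outside image", call. = FALSE)
  xs <- (seq_len(nx) - 1) * pixel_size_um - cx
  ys <- (seq_len(ny) - 1) * pixel_size_um - cy
  r <- sqrt(outer(ys^2, xs^2, "+"))
  n_bins <- as.integer(ceiling(R_um / radial_bin_um))
  bin <- floor(r / radial_bin_um) + 1L
  keep <- bin <= n_bins & r <= R_um   # profile stops at the droplet edge
  sums <- tapply(img[keep], bin[keep], sum)
  cnts <- tapply(img[keep], bin[keep], length)
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    r_lo_um = (seq_len(n_bins) - 1L) * radial_bin_um,
    r_mid_um = (seq_len(n_bins) - 0.5) * radial_bin_um,
    mean_intensity = NA_real_,
    n_px = 0L
  )
  ids <- as.integer(names(sums))
  out$mean_intensity[ids] <- as.numeric(sums) / as.numeric(cnts)
  out$n_px[ids] <- as.integer(cnts)
  out
}
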