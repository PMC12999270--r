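#' Calibrated multi-dimensional image stack
#'
#' An `image_stack` holds a 5-D fluorescence intensity array in the fixed
#' axis order T (time) x Z (focal slice) x C (channel) x Y x X together with
#' its physical calibration. All pipeline stages consume and produce this one
#' canonical layout; readers reorder axes on ingest.
#'
#' Pixel indices are 1-based in R; physical coordinates are pixel centers,
#' with the top-left pixel center of the first slice at (0, 0) um. The
#' physical x coordinate of column `j` is `(j - 1) * pixel_size_um`, and
#' likewise for y and z.
#'
#' @param data Numeric array. Arrays with fewer than 5 dimensions are
#'   promoted by prepending unit T/Z/C axes (a 2-D Y x X image becomes
#'   T = Z = C = 1).
#' @param pixel_size_um Pixel size in micrometres (isotropic in XY).
#' @param frame_interval_min Minutes between consecutive time points.
#' @param z_step_um Micrometres between consecutive z slices.
#' @param channel_names Character vector naming the C channels, e.g.
#'   `c("RNA", "protein")`.
#' @param t0_offset_min Minutes elapsed between system initialization
#'   (droplet formation) and the first acquired frame. Used when converting
#'   frame indices to absolute experiment times.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data,
                        pixel_size_um,
                        frame_interval_min,
                        z_step_um = 1,
                        channel_names = NULL,
                        t0_offset_min = 8) {
  if (!is.array(data) && !is.matrix(data)) {
    if (is.numeric(data)) data <- as.array(data) else
      stop("`data` must be a numeric array", call. = FALSE)
  }
  nd <- length(dim(data))
  if (nd > 5L) stop("`data` has more than 5 dimensions", call. = FALSE)
  if (nd < 5L) {
    # promote missing leading axes: ...YX -> TZCYX
    dim(data) <- c(rep(1L, 5L - nd), dim(data))
  }
  if (any(dim(data) < 1L)) stop("all stack dimensions must be >= 1", call. = FALSE)
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L)
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a positive finite number", call. = FALSE)
  if (!is.finite(frame_interval_min) || frame_interval_min <= 0)
    stop("`frame_interval_min` must be a positive finite number", call. = FALSE)
  if (!is.finite(z_step_um) || z_step_um <= 0)
    stop("`z_step_um` must be a positive finite number", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("stack intensities must be finite", call. = FALSE)
  if (any(data < 0))
    stop("stack intensities must be non-negative", call. = FALSE)
  nc <- dim(data)[3L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("`channel_names` length must equal the number of channels (", nc, ")",
         call. = FALSE)
  structure(
    list(
      data = data,
      pixel_size_um = as.numeric(pixel_size_um),
      z_step_um = as.numeric(z_step_um),
      frame_interval_min = as.numeric(frame_interval_min),
      channel_names = as.character(channel_names),
      t0_offset_min = as.numeric(t0_offset_min)
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("<image_stack> T=", d[1], " Z=", d[2], " C=", d[3],
      " Y=", d[4], " X=", d[5], "\n", sep = "")
  cat("  channels: ", paste(x$channel_names, collapse = ", "), "\n", sep = "")
  cat("  pixel ", x$pixel_size_um, " um, z step ", x$z_step_um,
      " um, frame interval ", x$frame_interval_min, " min, t0 offset ",
      x$t0_offset_min, " min\n", sep = "")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Dimensions of an image stack as a named vector
#' @param stack An `image_stack`.
#' @return Named integer vector with entries T, Z, C, Y, X.
#' @export
stack_dims <- function(stack) {
  d <- dim(stack$data)
  stats::setNames(d, c("T", "Z", "C", "Y", "X"))
}

#' Absolute experiment times of the frames in a stack
#'
#' @param stack An `image_stack`.
#' @return Numeric vector of length T: minutes since system initialization,
#'   `t0_offset_min + (frame - 1) * frame_interval_min`.
#' @export
frame_times <- function(stack) {
  stack$t0_offset_min +
    (seq_len(dim(stack$data)[1L]) - 1L) * stack$frame_interval_min
}

channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
    if (ch < 1L || ch > dim(stack$data)[3L])
      stop("channel index out of range: ", channel, call. = FALSE)
    return(ch)
  }
  ch <- match(channel, stack$channel_names)
  if (is.na(ch))
    stop("unknown channel \"", channel, "\"; available: ",
         paste(stack$channel_names, collapse = ", "), call. = FALSE)
  ch
}

#' Extract one Y x X slice from a stack
#'
#' @param stack An `image_stack`.
#' @param frame Time index (1-based).
#' @param z Z-slice index (1-based).
#' @param channel Channel name or index.
#' @return A Y x X numeric matrix.
#' @export
get_slice <- function(stack, frame, z, channel) {
  ch <- channel_index(stack, channel)
  d <- dim(stack$data)
  stopifnot(frame >= 1, frame <= d[1], z >= 1, z <= d[2])
  matrix(stack$data[frame, z, ch, , ], nrow = d[4], ncol = d[5])
}

#' Extract a Z x Y x X volume for one frame and channel
#'
#' @inheritParams get_slice
#' @return A Z x Y x X numeric array.
#' @export
get_volume <- function(stack, frame, channel) {
  ch <- channel_index(stack, channel)
  d <- dim(stack$data)
  stopifnot(frame >= 1, frame <= d[1])
  array(stack$data[frame, , ch, , ], dim = d[c(2, 4, 5)])
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read an image stack from a TIFF file
#'
#' Reads a multi-page TIFF written by [write_stack()] (pages ordered T-major,
#' then Z, then C) together with its JSON metadata sidecar (`<path>.json`),
#' which carries the axis sizes and the physical calibration. For TIFFs from
#' other sources the sidecar is absent and calibration and axis sizes must be
#' supplied as overrides; a 2-D single-page file is then promoted to
#' T = Z = C = 1.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um,frame_interval_min,z_step_um,channel_names,t0_offset_min
#'   Optional overrides; each takes precedence over the sidecar value.
#' @param axes Optional named integer vector `c(T=,Z=,C=)` giving axis sizes
#'   when no sidecar is present and the file holds more than one page.
#'
#' @return An [image_stack()].
#' @export
read_stack <- function(path,
                       pixel_size_um = NULL,
                       frame_interval_min = NULL,
                       z_step_um = NULL,
                       channel_names = NULL,
                       t0_offset_min = NULL,
                       axes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::fromJSON(sp, simplifyVector = TRUE)

  pick <- function(override, key, default = NULL) {
    if (!is.null(override)) return(override)
    if (!is.null(meta[[key]])) return(meta[[key]])
    default
  }
  px <- pick(pixel_size_um, "pixel_size_um")
  fi <- pick(frame_interval_min, "frame_interval_min")
  zs <- pick(z_step_um, "z_step_um", 1)
  cn <- pick(channel_names, "channel_names")
  t0 <- pick(t0_offset_min, "t0_offset_min", 8)

  missing <- c(
    if (is.null(px)) "pixel_size_um",
    if (is.null(fi)) "frame_interval_min"
  )
  if (length(missing) > 0)
    stop("missing calibration for ", basename(path), ": ",
         paste(missing, collapse = ", "),
         " (no metadata sidecar; supply overrides)", call. = FALSE)

  if (!is.null(axes)) {
    ax <- c(T = unname(axes["T"]), Z = unname(axes["Z"]), C = unname(axes["C"]))
  } else if (!is.null(meta$axes)) {
    ax <- unlist(meta$axes)[c("T", "Z", "C")]
  } else {
    ax <- c(T = length(pages), Z = 1L, C = 1L)
  }
  ax[is.na(ax)] <- 1L
  ax <- as.integer(ax)
  if (prod(ax) != length(pages))
    stop("axis sizes T*Z*C = ", prod(ax), " do not match page count ",
         length(pages), call. = FALSE)

  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  data <- array(0, dim = c(ax[1], ax[2], ax[3], ny, nx))
  k <- 0L
  for (t in seq_len(ax[1])) for (z in seq_len(ax[2])) for (ch in seq_len(ax[3])) {
    k <- k + 1L
    data[t, z, ch, , ] <- pages[[k]] * scale
  }
  image_stack(data,
              pixel_size_um = px, frame_interval_min = fi, z_step_um = zs,
              channel_names = cn, t0_offset_min = t0)
}

#' Write an image stack to a TIFF file with a metadata sidecar
#'
#' Pages are written T-major (then Z, then C). Non-negative integer-valued
#' data up to 65535 are stored as 16-bit samples and round-trip bit-exactly
#' through [read_stack()]; other data are rescaled to 16-bit with the scale
#' recorded in the sidecar (values then round-trip to ~1e-4 relative).
#' Calibration and axis sizes are written to `<path>.json`.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  is_int16 <- all(stack$data == round(stack$data)) && max(stack$data) <= 65535
  scale <- if (is_int16) 1 else max(stack$data) / 65535
  if (scale == 0) scale <- 1
  pages <- vector("list", prod(d[1:3]))
  k <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    k <- k + 1L
    pages[[k]] <- matrix(round(stack$data[t, z, ch, , ] / scale) / 65535,
                         nrow = d[4], ncol = d[5])
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write TIFF to ", path, call. = FALSE)
  meta <- list(
    axes = list(T = d[1], Z = d[2], C = d[3], Y = d[4], X = d[5]),
    pixel_size_um = stack$pixel_size_um,
    z_step_um = stack$z_step_um,
    frame_interval_min = stack$frame_interval_min,
    channel_names = stack$channel_names,
    t0_offset_min = stack$t0_offset_min,
    intensity_scale = scale
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
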