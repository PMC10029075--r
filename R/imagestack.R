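#' Multichannel image stack
#'
#' The canonical in-memory container for all images in the pipeline: a
#' 4-dimensional intensity array in `(channel, z, y, x)` order with physical
#' pixel metadata. 2D images are carried with a singleton z dimension.
#' Intensities are stored as doubles regardless of the on-disk dtype; the
#' original dtype is recorded for write-back.
#'
#' @param data numeric array. Accepted shapes: `(y, x)` (promoted to
#'   `(1, 1, y, x)`), `(z, y, x)` (promoted to one channel), or the canonical
#'   `(c, z, y, x)`.
#' @param pixel_size_xy lateral pixel size, micrometres per pixel.
#' @param pixel_size_z axial plane spacing, micrometres; required (> 0) when
#'   there is more than one z plane.
#' @param channel_names character vector, one label per channel.
#' @param expansion_factor linear expansion factor already applied to the
#'   pixel sizes, or `NA` when the stack is in raw (physical) scale.
#' @param dtype storage dtype recorded for write-back, `"float32"` or
#'   `"uint16"`.
#' @return an object of class `ImageStack` with elements `data`,
#'   `pixel_size_xy`, `pixel_size_z`, `channel_names`, `expansion_factor`,
#'   `dtype`.
#' @examples
#' st <- image_stack(array(runif(2 * 4 * 8 * 8), c(2, 4, 8, 8)),
#'                   pixel_size_xy = 0.108, pixel_size_z = 0.3)
#' dim(st$data)
#' @export
image_stack <- function(data, pixel_size_xy = NULL, pixel_size_z = NULL,
                        channel_names = NULL, expansion_factor = NA_real_,
                        dtype = "float32") {
  if (is.matrix(data)) data <- array(data, c(1L, 1L, dim(data)))
  if (length(dim(data)) == 3L) data <- array(data, c(1L, dim(data)))
  if (length(dim(data)) != 4L)
    stop("`data` must have 2, 3 or 4 dimensions, got ", length(dim(data)))
  storage.mode(data) <- "double"
  if (any(!is.finite(data))) stop("image intensities must be finite")
  if (any(data < 0)) stop("image intensities must be >= 0")
  d <- dim(data)
  if (is.null(pixel_size_xy)) {
    warning("pixel_size_xy missing; defaulting to 1.0 um/px")
    pixel_size_xy <- 1.0
  }
  if (pixel_size_xy <= 0) stop("pixel_size_xy must be > 0")
  if (d[2] > 1L) {
    if (is.null(pixel_size_z)) {
      warning("pixel_size_z missing for a multi-plane stack; defaulting to 1.0 um")
      pixel_size_z <- 1.0
    }
    if (pixel_size_z <= 0) stop("pixel_size_z must be > 0")
  } else {
    pixel_size_z <- pixel_size_z %||% 1.0
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[1]))
  if (length(channel_names) != d[1])
    stop("channel_names length (", length(channel_names),
         ") does not match channel dimension (", d[1], ")")
  structure(
    list(data = data, pixel_size_xy = pixel_size_xy, pixel_size_z = pixel_size_z,
         channel_names = as.character(channel_names),
         expansion_factor = expansion_factor, dtype = dtype),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d channel(s) x %d plane(s) x %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  pixel size: %.4g um/px (xy), %.4g um (z)\n",
              x$pixel_size_xy, x$pixel_size_z))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  if (!is.na(x$expansion_factor))
    cat(sprintf("  expansion factor applied: %.3f (biological scale)\n",
                x$expansion_factor))
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

#' Fluorescence time-series movie
#'
#' A single-channel frame sequence used for fluctuation (SOFI) imaging,
#' indexed `(t, y, x)`.
#'
#' @param frames numeric array `(t, y, x)`, `t >= 2`.
#' @param frame_interval seconds between frames.
#' @param pixel_size_xy micrometres per pixel.
#' @return an object of class `Movie`.
#' @export
movie <- function(frames, frame_interval = 0.1, pixel_size_xy = 1.0) {
  if (length(dim(frames)) != 3L) stop("`frames` must be a (t, y, x) array")
  if (dim(frames)[1] < 2L) stop("a Movie needs at least 2 frames")
  storage.mode(frames) <- "double"
  if (any(!is.finite(frames))) stop("frame intensities must be finite")
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_size_xy = pixel_size_xy),
            class = "Movie")
}

#' @export
print.Movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Movie: %d frames of %d x %d px, %.3g s/frame\n",
              d[1], d[2], d[3], x$frame_interval))
  invisible(x)
}

#' Maximum-intensity z projection
#'
#' Pixelwise maximum over a half-open window of z planes of one channel, the
#' projection used to pair a single pre-expansion plane with the 5-30 plane
#' post-expansion window that best matches it.
#'
#' @param stack an [image_stack()].
#' @param channel 0-based channel index.
#' @param z_window integer vector `c(start, stop)`, half-open 0-based plane
#'   range `[start, stop)`; default projects the full depth.
#' @return a numeric `(y, x)` matrix.
#' @export
max_project <- function(stack, channel = 0L, z_window = NULL) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  if (channel < 0L || channel >= d[1]) stop("channel index out of range")
  if (is.null(z_window)) z_window <- c(0L, d[2])
  start <- z_window[1]; stop_ <- z_window[2]
  if (stop_ <= start || start < 0L || stop_ > d[2])
    stop("z_window [", start, ", ", stop_, ") is empty or outside depth ", d[2])
  planes <- stack$data[channel + 1L, (start + 1L):stop_, , , drop = FALSE]
  apply(planes, c(3, 4), max)
}
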