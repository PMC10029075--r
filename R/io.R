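#' Read a multichannel TIFF stack
#'
#' Reads a (possibly multi-page) TIFF into the canonical `(c, z, y, x)`
#' order. Page layout and metadata are taken from the JSON sidecar written by
#' [write_stack()] when present (`<path>.json`); for foreign TIFFs the pages
#' are interpreted according to `axis_order_hint`.
#'
#' Missing pixel-size metadata defaults to 1.0 micrometre with a warning,
#' never silently.
#'
#' @param path TIFF file path.
#' @param axis_order_hint for files without a sidecar: `"z"` (pages are
#'   planes of a single channel), `"c"` (pages are channels of a single
#'   plane), or `"cz"` with `n_channels` pages interleaved channel-fastest.
#' @param n_channels channel count used with `axis_order_hint = "cz"`.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, axis_order_hint = NULL, n_channels = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("unreadable TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1] else p   # collapse RGB pages
  })
  np <- length(pages)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL

  if (!is.null(meta)) {
    nc <- meta$n_channels; nz <- meta$n_z
  } else if (np == 1L) {
    nc <- 1L; nz <- 1L
  } else if (identical(axis_order_hint, "z")) {
    nc <- 1L; nz <- np
  } else if (identical(axis_order_hint, "c")) {
    nc <- np; nz <- 1L
  } else if (identical(axis_order_hint, "cz")) {
    if (is.null(n_channels)) stop("axis_order_hint 'cz' requires n_channels")
    nc <- as.integer(n_channels); nz <- np %/% nc
    if (nc * nz != np) stop("page count ", np, " is not a multiple of n_channels ", nc)
  } else {
    stop("ambiguous axes for ", np, " pages of ",
         nrow(pages[[1]]), "x", ncol(pages[[1]]),
         "; pass axis_order_hint ('z', 'c' or 'cz')")
  }

  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, c(nc, nz, ny, nx))
  k <- 1L
  for (z in seq_len(nz)) for (ch in seq_len(nc)) {   # channel-fastest page order
    data[ch, z, , ] <- pages[[k]]; k <- k + 1L
  }
  scale <- meta$intensity_scale %||% 1.0
  data <- data * scale
  image_stack(data,
              pixel_size_xy = meta$pixel_size_xy,
              pixel_size_z = meta$pixel_size_z,
              channel_names = meta$channel_names,
              expansion_factor = meta$expansion_factor %||% NA_real_,
              dtype = meta$dtype %||% "float32")
}

#' Write a multichannel TIFF stack
#'
#' Writes the stack as a multi-page TIFF (pages channel-fastest within z) plus
#' a JSON metadata sidecar at `<path>.json` holding the axis layout, pixel
#' sizes, channel names, expansion factor and intensity scale. TIFF samples
#' are stored in `[0, 1]`: integer-valued data within 16 bits go through the
#' lossless 16-bit path; everything else is max-scaled 32-bit float.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  x <- stack$data
  int16 <- identical(stack$dtype, "uint16") ||
    (max(x) <= 65535 && all(x == round(x)))
  if (int16) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- max(x, 1e-300)
    bits <- 32L
  }
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (z in seq_len(d[2])) for (ch in seq_len(d[1])) {
    pages[[k]] <- x[ch, z, , ] / scale; k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "LZW")
  meta <- list(n_channels = d[1], n_z = d[2],
               pixel_size_xy = stack$pixel_size_xy,
               pixel_size_z = stack$pixel_size_z,
               channel_names = stack$channel_names,
               expansion_factor = stack$expansion_factor,
               intensity_scale = scale,
               dtype = if (int16) "uint16" else "float32")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
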