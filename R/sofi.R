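#' Drift and intensity correction of a fluctuation movie
#'
#' Each frame is translated by the subpixel shift (phase correlation against
#' the temporal mean, two refinement passes, ~0.1 px precision) that
#' maximizes its cross-correlation to the mean, then divided by its spatial
#' mean and rescaled to the global mean so slow intensity drift cancels.
#' Borders invalidated by the maximum drift are cropped.
#'
#' @param mv a [movie()].
#' @param n_passes refinement passes against the running mean.
#' @return a corrected [movie()] with attributes `"drift_track"` (per-frame
#'   `(dy, dx)`, px) and `"intensity_factors"`.
#' @export
correct_drift_intensity <- function(mv, n_passes = 2L) {
  stopifnot(inherits(mv, "Movie"))
  fr <- mv$frames
  nt <- dim(fr)[1]; ny <- dim(fr)[2]; nx <- dim(fr)[3]
  drift <- matrix(0, nt, 2)
  cur <- fr
  for (pass in seq_len(n_passes)) {
    ref <- apply(cur, c(2, 3), mean)
    step <- matrix(0, nt, 2)
    for (t in seq_len(nt)) step[t, ] <- estimate_shift(ref, cur[t, , ])
    # mechanical drift is smooth in time; a running median rejects the
    # spurious estimates sparse-blinking frames occasionally produce
    if (nt >= 5) {
      k <- min(7L, (nt %/% 2) * 2 - 1)
      step <- apply(step, 2, stats::runmed, k = k, endrule = "med")
    }
    drift <- drift + step
    if (any(abs(drift) > 0.25 * rep(c(ny, nx), each = nt)))
      stop("registration failure: drift exceeds 25% of the frame size")
    for (t in seq_len(nt))
      cur[t, , ] <- fft_shift_image(fr[t, , ], -drift[t, 1], -drift[t, 2])
  }
  gmean <- mean(cur)
  fac <- numeric(nt)
  for (t in seq_len(nt)) {
    m <- mean(cur[t, , ])
    fac[t] <- gmean / m
    cur[t, , ] <- cur[t, , ] * fac[t]
  }
  mdrift <- max(abs(drift))
  crop <- if (mdrift < 1e-6) 0L else ceiling(mdrift - 1e-9)
  if (crop > 0) {
    if (2 * crop >= min(ny, nx)) stop("registration failure: drift crops away the frame")
    cur <- cur[, (crop + 1):(ny - crop), (crop + 1):(nx - crop), drop = FALSE]
  }
  out <- movie(cur, frame_interval = mv$frame_interval,
               pixel_size_xy = mv$pixel_size_xy)
  attr(out, "drift_track") <- drift
  attr(out, "intensity_factors") <- fac
  out
}

#' Second-order cross-cumulant SOFI reconstruction
#'
#' Zero-lag second-order cumulants of the pixel time series after mean
#' subtraction (`dF = F - <F>_t`): each physical pixel gets its temporal
#' auto-cumulant `<dF^2>`, and each virtual in-between pixel on the doubled
#' grid gets the cross-cumulant of its flanking physical pixels
#' (`<dF_a dF_b>`; diagonal virtual pixels average the two diagonal pairs).
#' Uncorrelated noise cancels in the cross terms and the squared PSF narrows
#' by sqrt(2), which is the resolution gain. The standard absolute-value
#' convention is applied. For a 3D series, run per z-plane movie.
#'
#' @param mv a [movie()], ideally drift/intensity corrected, >= 50 frames
#'   recommended.
#' @return object of class `SofiResult`: `xc2_image` (`(2*ny-1) x (2*nx-1)`,
#'   virtual grid at half-pixel pitch), `deconvolved` (`NULL` until
#'   [lucy_richardson()] is applied), `n_frames_used`, `drift_track` (from
#'   the input attribute, if any), `pixel_size_xy` (half the input pitch).
#' @export
sofi_xc2 <- function(mv) {
  stopifnot(inherits(mv, "Movie"))
  fr <- mv$frames
  nt <- dim(fr)[1]; ny <- dim(fr)[2]; nx <- dim(fr)[3]
  mu <- apply(fr, c(2, 3), mean)
  dF <- sweep(fr, c(2, 3), mu)
  if (max(abs(dF)) == 0) {
    warning("constant movie: cumulant image is identically zero")
  }
  cum <- function(a, b) apply(a * b, c(2, 3), mean)   # <dFa dFb> over t
  auto <- cum(dF, dF)                                              # ny x nx
  out <- matrix(0, 2 * ny - 1, 2 * nx - 1)
  out[seq(1, 2 * ny - 1, 2), seq(1, 2 * nx - 1, 2)] <- auto
  if (ny > 1) {
    vy <- cum(dF[, -ny, , drop = FALSE], dF[, -1, , drop = FALSE]) # (ny-1) x nx
    out[seq(2, 2 * ny - 2, 2), seq(1, 2 * nx - 1, 2)] <- vy
  }
  if (nx > 1) {
    vx <- cum(dF[, , -nx, drop = FALSE], dF[, , -1, drop = FALSE]) # ny x (nx-1)
    out[seq(1, 2 * ny - 1, 2), seq(2, 2 * nx - 2, 2)] <- vx
  }
  if (ny > 1 && nx > 1) {
    d1 <- cum(dF[, -ny, -nx, drop = FALSE], dF[, -1, -1, drop = FALSE])
    d2 <- cum(dF[, -1, -nx, drop = FALSE], dF[, -ny, -1, drop = FALSE])
    out[seq(2, 2 * ny - 2, 2), seq(2, 2 * nx - 2, 2)] <- 0.5 * (d1 + d2)
  }
  structure(list(xc2_image = abs(out), deconvolved = NULL,
                 n_frames_used = nt,
                 drift_track = attr(mv, "drift_track"),
                 pixel_size_xy = mv$pixel_size_xy / 2),
            class = "SofiResult")
}

#' @export
print.SofiResult <- function(x, ...) {
  cat(sprintf("SofiResult: XC2 image %d x %d (virtual half-pixel grid), %d frames%s\n",
              nrow(x$xc2_image), ncol(x$xc2_image), x$n_frames_used,
              if (!is.null(x$deconvolved)) ", deconvolved" else ""))
  invisible(x)
}

#' Richardson-Lucy deconvolution
#'
#' The standard multiplicative expectation-maximization update for Poisson
#' imaging, `est <- est * conv(obs / conv(est, psf), flip(psf))`, iterated
#' `n_iter` times from a flat start. Non-negativity is preserved by
#' construction and total flux is conserved for interior-supported objects.
#'
#' @param image non-negative 2D matrix.
#' @param psf 2D kernel summing to 1 (use [gaussian_psf()] for a Gaussian).
#' @param n_iter iterations (>= 1; 10 is the package default elsewhere).
#' @return deconvolved matrix of the same size.
#' @export
lucy_richardson <- function(image, psf, n_iter = 10L) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  s <- sum(psf)
  if (!is.finite(s) || s <= 0) stop("psf is not normalizable (sum <= 0)")
  if (abs(s - 1) > 1e-6) stop("psf must be normalized to sum 1")
  if (min(image) < -1e-8 * max(abs(image))) stop("image must be non-negative")
  image <- pmax(image, 0)
  est <- matrix(mean(image), nrow(image), ncol(image))
  psf_m <- psf[rev(seq_len(nrow(psf))), rev(seq_len(ncol(psf))), drop = FALSE]
  eps <- 1e-12
  for (it in seq_len(n_iter)) {
    den <- conv2_same(est, psf)
    est <- est * conv2_same(image / pmax(den, eps), psf_m)
    est[est < 0] <- 0   # guard FFT round-off
  }
  est
}

#' Gaussian PSF kernel
#'
#' @param sigma Gaussian sigma in pixels.
#' @param radius half-width of the support (default 4 sigma).
#' @return odd-sized kernel matrix summing to 1.
#' @export
gaussian_psf <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  gaussian_kernel(sigma, radius)
}

#' Full SOFI pipeline for one z-plane movie
#'
#' Drift/intensity correction, second-order cumulant reconstruction, and
#' Richardson-Lucy deconvolution with a Gaussian PSF. The XC2 PSF is the
#' square of the optical PSF, so the deconvolution kernel sigma is the
#' optical sigma divided by sqrt(2) (on the half-pitch virtual grid: times 2
#' grid units per optical pixel... handled internally).
#'
#' @param mv a [movie()].
#' @param psf_sigma optical PSF sigma in *input* pixels; `NULL` estimates it
#'   from the brightest isolated spot of the mean image.
#' @param n_iter Richardson-Lucy iterations.
#' @return a `SofiResult` with `deconvolved` filled in.
#' @export
sofi_reconstruct <- function(mv, psf_sigma = NULL, n_iter = 10L) {
  mvc <- correct_drift_intensity(mv)
  res <- sofi_xc2(mvc)
  if (is.null(psf_sigma)) {
    mu <- apply(mvc$frames, c(2, 3), mean)
    psf_sigma <- spot_sigma(mu)
  }
  # XC2 PSF sigma on the virtual grid: optical sigma / sqrt(2), times 2
  # virtual pixels per physical pixel
  sig_v <- psf_sigma / sqrt(2) * 2
  res$deconvolved <- lucy_richardson(res$xc2_image, gaussian_psf(sig_v), n_iter)
  res
}
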