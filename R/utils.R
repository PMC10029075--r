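# Internal numeric helpers shared across the pipeline. All images are plain
# numeric matrices indexed [y, x] (row = y), 0-based pixel-centre coordinates
# at the user-facing interfaces, 1-based internally where R indexing demands.

# Run code with a temporary RNG state derived from `seed`, restoring the
# caller's stream afterwards so library calls never perturb user simulations.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Squared angular-frequency grid for an n1 x n2 FFT (omega^2 = wy^2 + wx^2).
.omega2 <- function(n1, n2) {
  fy <- c(0:floor(n1 / 2), -(ceiling(n1 / 2) - 1):-1)[1:n1] / n1
  fx <- c(0:floor(n2 / 2), -(ceiling(n2 / 2) - 1):-1)[1:n2] / n2
  outer((2 * pi * fy)^2, (2 * pi * fx)^2, `+`)
}

# Gaussian blur with periodic boundary, exact transfer function exp(-sigma^2 w^2 / 2).
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  h <- exp(-0.5 * sigma^2 * .omega2(nrow(img), ncol(img)))
  Re(stats::fft(stats::fft(img) * h, inverse = TRUE)) / length(img)
}

# Scale-normalized negative Laplacian-of-Gaussian response stack (positive at
# bright blob centres). Returns a [y, x, scale] array.
log_response_stack <- function(img, sigmas) {
  F0 <- stats::fft(img)
  w2 <- .omega2(nrow(img), ncol(img))
  out <- array(0, c(dim(img), length(sigmas)))
  for (k in seq_along(sigmas)) {
    s <- sigmas[k]
    h <- s^2 * w2 * exp(-0.5 * s^2 * w2)
    out[, , k] <- Re(stats::fft(F0 * h, inverse = TRUE)) / length(img)
  }
  out
}

# Bilinear interpolation of `img` at (y, x) in 0-based pixel-centre coords.
# Out-of-range samples clamp to the border.
interp2 <- function(img, y, x) {
  y <- as.numeric(y); x <- as.numeric(x)
  ny <- nrow(img); nx <- ncol(img)
  y <- pmin(pmax(y, 0), ny - 1)
  x <- pmin(pmax(x, 0), nx - 1)
  y0 <- pmin(floor(y), ny - 2); x0 <- pmin(floor(x), nx - 2)
  dy <- y - y0; dx <- x - x0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i10 <- img[cbind(y0 + 2, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x0 + 2)]
  i11 <- img[cbind(y0 + 2, x0 + 2)]
  i00 * (1 - dy) * (1 - dx) + i10 * dy * (1 - dx) +
    i01 * (1 - dy) * dx + i11 * dy * dx
}

# Subpixel translation by (dy, dx) using the Fourier shift theorem
# (periodic boundary). Positive dy moves content toward larger y.
fft_shift_image <- function(img, dy, dx) {
  n1 <- nrow(img); n2 <- ncol(img)
  fy <- c(0:floor(n1 / 2), -(ceiling(n1 / 2) - 1):-1)[1:n1] / n1
  fx <- c(0:floor(n2 / 2), -(ceiling(n2 / 2) - 1):-1)[1:n2] / n2
  ph <- exp(-2i * pi * (outer(fy * dy, fx * dx, `+`)))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (n1 * n2)
}

# Phase-correlation shift estimate: the (dy, dx) by which `img` is translated
# relative to `ref` (img ~ ref shifted by +(dy,dx)), subpixel via 3-point
# parabolic interpolation of the correlation peak.
phase_corr_shift <- function(ref, img, eps = 1e-12, whiten = TRUE) {
  if (!whiten) { ref <- ref - mean(ref); img <- img - mean(img) }
  Fa <- stats::fft(ref); Fb <- stats::fft(img)
  R <- Fa * Conj(Fb)
  if (whiten) R <- R / (Mod(R) + eps)
  c2 <- Re(stats::fft(R, inverse = TRUE)) / length(ref)
  pk <- which(c2 == max(c2), arr.ind = TRUE)[1, ]
  n1 <- nrow(c2); n2 <- ncol(c2)
  sub <- function(mat, i, j) mat[(i - 1) %% n1 + 1, (j - 1) %% n2 + 1]
  para <- function(a, b, c) {
    d <- a - 2 * b + c
    if (abs(d) < 1e-12) 0 else 0.5 * (a - c) / d
  }
  oy <- para(sub(c2, pk[1] - 1, pk[2]), c2[pk[1], pk[2]], sub(c2, pk[1] + 1, pk[2]))
  ox <- para(sub(c2, pk[1], pk[2] - 1), c2[pk[1], pk[2]], sub(c2, pk[1], pk[2] + 1))
  dy <- pk[1] - 1 + oy; dx <- pk[2] - 1 + ox
  if (dy > n1 / 2) dy <- dy - n1
  if (dx > n2 / 2) dx <- dx - n2
  # cross-correlation peak of ref against img at lag (dy,dx) means img is
  # displaced by -(dy,dx); flip so the return value is img's displacement
  c(dy = -dy, dx = -dx)
}

# Iteratively refined subpixel shift estimate. Mean-subtracted (unwhitened)
# cross-correlation is used rather than phase correlation: whitening
# equalizes noise-dominated high frequencies, which biases the peak for
# smooth low-frequency images. The parabolic peak interpolation is biased
# for fractional shifts, but the bias vanishes as the residual shift
# approaches zero, so re-estimating after undoing the current estimate
# converges to ~0.01 px.
estimate_shift <- function(ref, img, n_refine = 4L, tol = 1e-3) {
  est <- c(dy = 0, dx = 0)
  for (i in seq_len(n_refine)) {
    res <- fft_shift_image(img, -est[1], -est[2])
    d <- phase_corr_shift(ref, res, whiten = FALSE)
    est <- est + d
    if (max(abs(d)) < tol) break
  }
  est
}

# 2D convolution, 'same' output, zero-padded boundary, via FFT.
conv2_same <- function(img, kern) {
  ni <- dim(img); nk <- dim(kern)
  n1 <- ni[1] + nk[1] - 1; n2 <- ni[2] + nk[2] - 1
  A <- matrix(0, n1, n2); A[1:ni[1], 1:ni[2]] <- img
  B <- matrix(0, n1, n2); B[1:nk[1], 1:nk[2]] <- kern
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (n1 * n2)
  off1 <- floor(nk[1] / 2); off2 <- floor(nk[2] / 2)
  full[(off1 + 1):(off1 + ni[1]), (off2 + 1):(off2 + ni[2])]
}

# Normalized 2D Gaussian kernel on an odd-sized support (~ +/- 4 sigma).
gaussian_kernel <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  x <- -radius:radius
  k <- exp(-0.5 * outer(x^2, x^2, `+`) / sigma^2)
  k / sum(k)
}

# Gaussian width of a single bright spot from its radial half-maximum:
# background = image median, centroid from pixels above half max, FWHM from
# the radial profile's half-max crossing (linear interpolation between 0.25
# px annuli). Robust to a flat noisy background, unlike raw moments.
spot_sigma <- function(img) {
  bg <- stats::median(img)
  pk <- max(img)
  if (pk <= bg) return(NA_real_)
  half <- bg + (pk - bg) / 2
  w <- which(img >= half, arr.ind = TRUE)
  wt <- img[w] - bg
  cy <- sum((w[, 1] - 1) * wt) / sum(wt)
  cx <- sum((w[, 2] - 1) * wt) / sum(wt)
  ys <- matrix(0:(nrow(img) - 1), nrow(img), ncol(img))
  xs <- matrix(0:(ncol(img) - 1), nrow(img), ncol(img), byrow = TRUE)
  r <- sqrt((ys - cy)^2 + (xs - cx)^2)
  bin <- floor(r / 0.25)
  prof <- unname(vapply(split(as.vector(img), bin), mean, numeric(1)))
  rad <- (as.numeric(names(split(as.vector(img), bin))) + 0.5) * 0.25
  o <- order(rad); prof <- prof[o]; rad <- rad[o]
  below <- which(prof <= half)
  if (length(below) == 0) return(NA_real_)
  k <- below[1]
  if (k == 1) return(rad[1] / 1.1774)
  # linear interpolation between the last annulus above and first below
  f <- (prof[k - 1] - half) / (prof[k - 1] - prof[k])
  hwhm <- rad[k - 1] + f * (rad[k] - rad[k - 1])
  hwhm / sqrt(2 * log(2))
}

# Smooth zero-mean random vector field: coarse i.i.d. normal grid upsampled by
# separable cubic splines, rescaled so the maximum displacement magnitude is
# `amplitude`. Returns list(dy, dx) matrices of size ny x nx.
smooth_random_field <- function(ny, nx, amplitude, grid = 6L) {
  if (amplitude <= 0) {
    z <- matrix(0, ny, nx)
    return(list(dy = z, dx = z))
  }
  up <- function(coarse) {
    gy <- seq(0, ny - 1, length.out = nrow(coarse))
    gx <- seq(0, nx - 1, length.out = ncol(coarse))
    # rows first: interpolate along x at each coarse row, then along y
    tmp <- t(apply(coarse, 1, function(r) stats::spline(gx, r, xout = 0:(nx - 1))$y))
    apply(tmp, 2, function(col) stats::spline(gy, col, xout = 0:(ny - 1))$y)
  }
  dy <- up(matrix(stats::rnorm(grid * grid), grid, grid))
  dx <- up(matrix(stats::rnorm(grid * grid), grid, grid))
  dy <- dy - mean(dy); dx <- dx - mean(dx)
  mag <- sqrt(dy^2 + dx^2)
  sc <- amplitude / max(mag)
  list(dy = dy * sc, dx = dx * sc)
}

# Render anisotropic Gaussian blobs into a ny x nx image.
# centers: matrix [n, 2] of (y, x) 0-based; sigmas: [n, 2] (sigma_y, sigma_x)
# in the blob's own frame; thetas: rotation of each blob; amps: peak values.
render_blobs <- function(ny, nx, centers, sigmas, thetas, amps) {
  img <- matrix(0, ny, nx)
  n <- nrow(centers)
  if (n == 0) return(img)
  for (i in seq_len(n)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]
    sy <- sigmas[i, 1]; sx <- sigmas[i, 2]; th <- thetas[i]
    r <- ceiling(4 * max(sy, sx))
    y0 <- max(0, floor(cy - r)); y1 <- min(ny - 1, ceiling(cy + r))
    x0 <- max(0, floor(cx - r)); x1 <- min(nx - 1, ceiling(cx + r))
    if (y0 > y1 || x0 > x1) next
    yy <- (y0:y1) - cy; xx <- (x0:x1) - cx
    ct <- cos(th); st <- sin(th)
    u <- outer(yy * ct, -xx * st, `+`)   # rotated coords
    v <- outer(yy * st, xx * ct, `+`)
    g <- amps[i] * exp(-0.5 * (u^2 / sy^2 + v^2 / sx^2))
    img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <-
      img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] + g
  }
  img
}

# 3D box-filter local mean with clamped (shrinking) windows at the borders,
# via integral volume. x: 3D array; w: odd window edge length.
box_mean_3d <- function(x, w) {
  d <- dim(x)
  h <- (w - 1L) / 2L
  # pad integral with a zero slab on each leading face
  S <- array(0, d + 1L)
  S[-1, -1, -1] <- x
  S <- apply(S, c(2, 3), cumsum)           # cumsum over dim1 -> [d1+1, d2+1, d3+1]
  S <- aperm(apply(S, c(1, 3), cumsum), c(2, 1, 3))
  S <- aperm(apply(S, c(1, 2), cumsum), c(2, 3, 1))
  lo <- function(n) pmax(0L, (1:n) - h - 1L)       # exclusive lower bound
  hi <- function(n) pmin(n, (1:n) + h)             # inclusive upper bound
  l1 <- lo(d[1]); u1 <- hi(d[1]); l2 <- lo(d[2]); u2 <- hi(d[2]); l3 <- lo(d[3]); u3 <- hi(d[3])
  sums <- array(0, d); cnts <- array(0, d)
  # inclusion-exclusion on the integral volume, vectorized over dim1
  for (j in 1:d[2]) for (k in 1:d[3]) {
    a2 <- u2[j] + 1L; b2 <- l2[j] + 1L; a3 <- u3[k] + 1L; b3 <- l3[k] + 1L
    sums[, j, k] <-
      S[u1 + 1L, a2, a3] - S[l1 + 1L, a2, a3] -
      S[u1 + 1L, b2, a3] + S[l1 + 1L, b2, a3] -
      S[u1 + 1L, a2, b3] + S[l1 + 1L, a2, b3] +
      S[u1 + 1L, b2, b3] - S[l1 + 1L, b2, b3]
    cnts[, j, k] <- (u1 - l1) * (u2[j] - l2[j]) * (u3[k] - l3[k])
  }
  sums / cnts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
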