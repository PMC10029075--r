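#' Scale-invariant keypoint detection
#'
#' Blob keypoints from scale-normalized Laplacian-of-Gaussian extrema:
#' a pixel is a keypoint when its negative-LoG response exceeds its 8 spatial
#' neighbours at its own scale and the 9 neighbours at the two adjacent
#' scales, with subpixel position and scale from 3-point parabolic
#' interpolation. Suited to the punctate, blob-like structure of fluorescence
#' images; the detected scale makes the downstream descriptors invariant to
#' the expansion factor.
#'
#' @param img numeric matrix `(y, x)`.
#' @param sigma_range range of blob scales (Gaussian sigma, px) to search.
#' @param n_per_octave scale sampling density.
#' @param thresh_rel response threshold relative to the strongest response.
#' @param max_keypoints keep at most this many, strongest first.
#' @return data.frame with columns `y`, `x` (0-based subpixel), `sigma`,
#'   `response`.
#' @export
detect_keypoints <- function(img, sigma_range = c(1.5, 24), n_per_octave = 3,
                             thresh_rel = 0.05, max_keypoints = 600L) {
  if (max(img) - min(img) <= 0) stop("insufficient keypoints: image is constant")
  n_oct <- log2(sigma_range[2] / sigma_range[1])
  n_lev <- max(3L, ceiling(n_oct * n_per_octave) + 1L)
  sigmas <- sigma_range[1] * 2^(seq(0, n_oct, length.out = n_lev))
  R <- log_response_stack(img, sigmas)
  ny <- dim(R)[1]; nx <- dim(R)[2]; ns <- dim(R)[3]
  thr <- thresh_rel * max(R)
  kp <- vector("list", ns)
  iy <- 2:(ny - 1); ix <- 2:(nx - 1)
  for (k in 2:(ns - 1)) {
    A <- R[, , k]
    C <- A[iy, ix]
    ismax <- C > thr &
      C > A[iy - 1, ix] & C > A[iy + 1, ix] &
      C > A[iy, ix - 1] & C > A[iy, ix + 1] &
      C > A[iy - 1, ix - 1] & C > A[iy - 1, ix + 1] &
      C > A[iy + 1, ix - 1] & C > A[iy + 1, ix + 1]
    for (kk in c(k - 1L, k + 1L)) {
      B <- R[, , kk]
      ismax <- ismax &
        C >= B[iy, ix] &
        C >= B[iy - 1, ix] & C >= B[iy + 1, ix] &
        C >= B[iy, ix - 1] & C >= B[iy, ix + 1] &
        C >= B[iy - 1, ix - 1] & C >= B[iy - 1, ix + 1] &
        C >= B[iy + 1, ix - 1] & C >= B[iy + 1, ix + 1]
    }
    w <- which(ismax, arr.ind = TRUE)
    if (nrow(w) == 0) next
    y0 <- w[, 1] + 1L; x0 <- w[, 2] + 1L   # back to full-image indices
    para <- function(a, b, c) {
      d <- a - 2 * b + c
      off <- ifelse(abs(d) < 1e-12, 0, 0.5 * (a - c) / d)
      pmin(pmax(off, -0.5), 0.5)
    }
    dy <- para(A[cbind(y0 - 1L, x0)], A[cbind(y0, x0)], A[cbind(y0 + 1L, x0)])
    dx <- para(A[cbind(y0, x0 - 1L)], A[cbind(y0, x0)], A[cbind(y0, x0 + 1L)])
    ds <- para(R[cbind(y0, x0, k - 1L)], A[cbind(y0, x0)], R[cbind(y0, x0, k + 1L)])
    lstep <- log(sigmas[2] / sigmas[1])
    kp[[k]] <- data.frame(y = y0 - 1 + dy, x = x0 - 1 + dx,
                          sigma = sigmas[k] * exp(ds * lstep),
                          response = A[cbind(y0, x0)])
  }
  out <- do.call(rbind, kp)
  if (is.null(out) || nrow(out) == 0) stop("insufficient keypoints: no blob extrema found")
  out <- out[order(-out$response), , drop = FALSE]
  # suppress duplicates found at neighbouring scales (within 1.5 px)
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {
      prev <- which(keep[1:(i - 1)])
      d2 <- (out$y[prev] - out$y[i])^2 + (out$x[prev] - out$x[i])^2
      if (any(d2 < 1.5^2)) keep[i] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  utils::head(out, max_keypoints)
}

# Log-polar patch descriptor, rotation-normalized by the intensity centroid
# orientation, scale-normalized by the detected blob sigma. Rings at
# radii_mult * sigma, 8 angular sectors, sampled bilinearly from a lightly
# smoothed image; zero-mean unit-norm.
.describe_keypoints <- function(img, kps, radii_mult = c(1, 2, 3, 4.5, 6, 8),
                                n_ang = 8L) {
  n <- nrow(kps)
  d <- length(radii_mult) * n_ang + 1L
  desc <- matrix(0, n, d)
  theta0 <- numeric(n)
  ang <- seq(0, 2 * pi, length.out = n_ang + 1L)[-(n_ang + 1L)]
  for (i in seq_len(n)) {
    cy <- kps$y[i]; cx <- kps$x[i]; s <- kps$sigma[i]
    # orientation: intensity centroid over a disc of radius 6 sigma
    r <- 6 * s
    g <- expand.grid(dy = seq(-r, r, length.out = 15), dx = seq(-r, r, length.out = 15))
    inside <- g$dy^2 + g$dx^2 <= r^2
    g <- g[inside, ]
    w <- interp2(img, cy + g$dy, cx + g$dx)
    m01 <- sum(w * g$dy); m10 <- sum(w * g$dx)
    th <- if (m01 == 0 && m10 == 0) 0 else atan2(m01, m10)
    theta0[i] <- th
    sy <- outer(radii_mult * s, sin(ang + th))
    sx <- outer(radii_mult * s, cos(ang + th))
    v <- c(interp2(img, cy, cx), interp2(img, cy + as.vector(sy), cx + as.vector(sx)))
    v <- v - mean(v)
    nv <- sqrt(sum(v^2))
    desc[i, ] <- if (nv > 0) v / nv else v
  }
  attr(desc, "orientation") <- theta0
  desc
}

#' Detect and match keypoints between two images
#'
#' Scale-invariant blob keypoints ([detect_keypoints()]) are described by
#' rotation- and scale-normalized log-polar patches and matched by descriptor
#' nearest neighbour with a ratio test (default 0.8). All surviving matches
#' are returned with `inlier_mask` unset; consensus filtering belongs to
#' [fit_similarity_ransac()].
#'
#' @param img_a,img_b numeric matrices; `img_a` is the source (pre) image.
#' @param ratio nearest/second-nearest descriptor distance ratio cutoff.
#' @param sigma_range_a,sigma_range_b blob scale search ranges per image
#'   (post-expansion images carry proportionally larger blobs).
#' @param max_keypoints per-image keypoint cap.
#' @return a [match_set()]; `scores` holds `1 - ratio` per match.
#' @export
detect_and_match_keypoints <- function(img_a, img_b, ratio = 0.8,
                                       sigma_range_a = c(1.5, 8),
                                       sigma_range_b = c(1.5, 48),
                                       max_keypoints = 600L) {
  ka <- detect_keypoints(img_a, sigma_range = sigma_range_a,
                         max_keypoints = max_keypoints)
  kb <- detect_keypoints(img_b, sigma_range = sigma_range_b,
                         max_keypoints = max_keypoints)
  da <- .describe_keypoints(img_a, ka)
  db <- .describe_keypoints(img_b, kb)
  # squared distances between unit vectors: 2 - 2 a.b
  cross <- tcrossprod(da, db)
  d2 <- pmax(2 - 2 * cross, 0)
  idx1 <- max.col(-d2, ties.method = "first")
  best <- d2[cbind(seq_len(nrow(d2)), idx1)]
  d2b <- d2; d2b[cbind(seq_len(nrow(d2)), idx1)] <- Inf
  second <- apply(d2b, 1, min)
  r <- sqrt(best) / pmax(sqrt(second), 1e-12)
  ok <- r <= ratio
  # mutual-consistency: keep one source per target (best ratio wins)
  sel <- which(ok)
  if (length(sel) > 1) {
    ord <- sel[order(r[sel])]
    seen <- logical(nrow(kb))
    keep <- logical(length(ord))
    for (i in seq_along(ord)) {
      t <- idx1[ord[i]]
      if (!seen[t]) { seen[t] <- TRUE; keep[i] <- TRUE }
    }
    sel <- ord[keep]
  }
  if (length(sel) < 4L)
    stop("insufficient keypoints: fewer than 4 descriptor matches survived; ",
         "supply a transform manually (e.g. similarity_transform()) to proceed")
  match_set(as.matrix(ka[sel, c("y", "x")]),
            as.matrix(kb[idx1[sel], c("y", "x")]),
            scores = 1 - r[sel])
}
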