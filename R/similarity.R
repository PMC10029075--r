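#' Similarity transform (rotation + translation + uniform scale)
#'
#' The geometric model linking pre- and post-expansion coordinates: isotropic
#' expansion only rescales, rotates and shifts the specimen, so the alignment
#' model deliberately permits nothing else. Maps `(y, x)` points as
#' `q = s * R(theta) %*% p + t`.
#'
#' @param scale positive scalar.
#' @param rotation radians, counter-clockwise in `(y, x)` with y down.
#' @param translation length-2 numeric `(ty, tx)` in pixels.
#' @return an object of class `SimilarityTransform`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0, translation = c(0, 0)) {
  if (scale <= 0) stop("scale must be > 0")
  structure(list(scale = scale, rotation = rotation,
                 translation = as.numeric(translation)),
            class = "SimilarityTransform")
}

#' @export
print.SimilarityTransform <- function(x, ...) {
  cat(sprintf("SimilarityTransform: scale %.6g, rotation %.6g rad, translation (%.4g, %.4g) px\n",
              x$scale, x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

#' Apply a similarity transform to points
#'
#' @param transform a [similarity_transform()].
#' @param pts matrix `[n, 2]` of `(y, x)` coordinates.
#' @return transformed `[n, 2]` matrix.
#' @export
apply_transform <- function(transform, pts) {
  pts <- rbind(pts)
  ct <- cos(transform$rotation); st <- sin(transform$rotation)
  y <- transform$scale * (ct * pts[, 1] - st * pts[, 2]) + transform$translation[1]
  x <- transform$scale * (st * pts[, 1] + ct * pts[, 2]) + transform$translation[2]
  cbind(y, x, deparse.level = 0)
}

#' Invert a similarity transform
#'
#' @param transform a [similarity_transform()].
#' @return the inverse `SimilarityTransform`; applying one after the other is
#'   the identity to machine precision.
#' @export
invert_transform <- function(transform) {
  s <- 1 / transform$scale
  th <- -transform$rotation
  t_inv <- -s * c(cos(th) * transform$translation[1] - sin(th) * transform$translation[2],
                  sin(th) * transform$translation[1] + cos(th) * transform$translation[2])
  similarity_transform(s, th, t_inv)
}

#' Paired keypoint set
#'
#' @param points_a,points_b matrices `[n, 2]` of matched `(y, x)` coordinates
#'   (a = source/pre image, b = target/post image).
#' @param scores per-match quality in `[0, 1]` (1 = best).
#' @param inlier_mask logical per match; `NA` until a consensus fit sets it.
#' @return an object of class `MatchSet`.
#' @export
match_set <- function(points_a, points_b, scores = NULL, inlier_mask = NULL) {
  points_a <- rbind(points_a); points_b <- rbind(points_b)
  if (nrow(points_a) != nrow(points_b)) stop("point sets differ in length")
  n <- nrow(points_a)
  structure(list(points_a = points_a, points_b = points_b,
                 scores = scores %||% rep(NA_real_, n),
                 inlier_mask = inlier_mask %||% rep(NA, n)),
            class = "MatchSet")
}

#' @export
print.MatchSet <- function(x, ...) {
  n <- nrow(x$points_a)
  ni <- sum(x$inlier_mask, na.rm = TRUE)
  cat(sprintf("MatchSet: %d matches%s\n", n,
              if (any(!is.na(x$inlier_mask))) sprintf(", %d inliers", ni) else ""))
  invisible(x)
}

# Closed-form least-squares similarity (no reflection) via complex regression:
# with centred points p~, q~ the optimum is a = sum(Conj(p~) q~) / sum(|p~|^2),
# scale = |a|, rotation = Arg(a). lock_scale = TRUE fits a rigid transform.
fit_similarity_ls <- function(pa, pb, lock_scale = FALSE) {
  p <- complex(real = pa[, 1], imaginary = pa[, 2])
  q <- complex(real = pb[, 1], imaginary = pb[, 2])
  mp <- mean(p); mq <- mean(q)
  pc <- p - mp; qc <- q - mq
  a <- sum(Conj(pc) * qc) / sum(Mod(pc)^2)
  if (lock_scale) a <- a / Mod(a)
  t_ <- mq - a * mp
  similarity_transform(Mod(a), Arg(a), c(Re(t_), Im(t_)))
}

# Exact similarity from a minimal 2-point sample.
fit_similarity_minimal <- function(pa, pb, lock_scale = FALSE) {
  p <- complex(real = pa[, 1], imaginary = pa[, 2])
  q <- complex(real = pb[, 1], imaginary = pb[, 2])
  dp <- p[1] - p[2]
  if (Mod(dp) < 1e-12) return(NULL)
  a <- (q[1] - q[2]) / dp
  if (Mod(a) < 1e-12) return(NULL)
  if (lock_scale) a <- a / Mod(a)
  t_ <- q[1] - a * p[1]
  similarity_transform(Mod(a), Arg(a), c(Re(t_), Im(t_)))
}

#' Consensus similarity fit (RANSAC)
#'
#' Random-sample-consensus fit of the similarity model to a match set:
#' minimal 2-point hypotheses, inliers scored at `inlier_tol` in the target
#' frame, followed by a closed-form least-squares refit on the consensus set.
#' Deterministic for a fixed `seed`.
#'
#' @param matches a [match_set()].
#' @param inlier_tol inlier residual tolerance, pixels in the target frame.
#' @param max_iter maximum sampling iterations.
#' @param seed integer seed for the hypothesis sampler.
#' @param lock_scale fit a rigid (scale = 1) transform, used for multi-round
#'   registration where no further expansion occurs between rounds.
#' @return list with `transform` ([similarity_transform()]), `matches` (the
#'   input with `inlier_mask` set), `n_inliers`, and `low_confidence` (TRUE
#'   when the inlier fraction is below 25%).
#' @export
fit_similarity_ransac <- function(matches, inlier_tol = 3, max_iter = 2000,
                                  seed = 1, lock_scale = FALSE) {
  pa <- matches$points_a; pb <- matches$points_b
  n <- nrow(pa)
  if (n < 2L) stop("need at least 2 matches to fit a similarity")
  best_mask <- NULL; best_n <- -1L
  resid2 <- function(tr) {
    pred <- apply_transform(tr, pa)
    rowSums((pred - pb)^2)
  }
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      idx <- sample.int(n, 2L)
      tr <- fit_similarity_minimal(pa[idx, , drop = FALSE], pb[idx, , drop = FALSE],
                                   lock_scale = lock_scale)
      if (is.null(tr)) next
      mask <- resid2(tr) <= inlier_tol^2
      ni <- sum(mask)
      if (ni > best_n) { best_n <- ni; best_mask <- mask }
      # early exit once a clear consensus exists
      if (best_n >= max(10L, 0.9 * n)) break
    }
  })
  if (is.null(best_mask) || best_n < 2L)
    stop("similarity fit failed: no consensus set found")
  tr <- fit_similarity_ls(pa[best_mask, , drop = FALSE], pb[best_mask, , drop = FALSE],
                          lock_scale = lock_scale)
  # refine: recompute inliers under the refit model, refit once more
  mask <- resid2(tr) <= inlier_tol^2
  if (sum(mask) >= 2L) {
    tr <- fit_similarity_ls(pa[mask, , drop = FALSE], pb[mask, , drop = FALSE],
                            lock_scale = lock_scale)
    best_mask <- mask
  }
  matches$inlier_mask <- as.logical(best_mask)
  ni <- sum(best_mask)
  if (ni == 0L) stop("similarity fit failed: zero inliers")
  low <- ni / n < 0.25
  if (low) warning("low-confidence fit: inlier fraction ", round(100 * ni / n), "%")
  list(transform = tr, matches = matches, n_inliers = ni, low_confidence = low)
}
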