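#' Distortion vector field from consensus matches
#'
#' The residual displacements left after the best similarity alignment are
#' the non-rigid distortion introduced by expansion. Each inlier contributes
#' `(transform(pre_point) - post_point) / scale * pixel_size_pre`: the
#' misfit measured in the post frame, brought back to pre-expansion
#' (biological) micrometres and anchored at its pre-image position.
#'
#' @param matches a [match_set()] with `inlier_mask` set (from
#'   [fit_similarity_ransac()]).
#' @param transform the fitted [similarity_transform()].
#' @param pixel_size_pre pre-expansion pixel size, um/px.
#' @return object of class `DistortionField`: `anchor_points` (`[n, 2]`, um)
#'   and `residual_vectors` (`[n, 2]`, um).
#' @export
distortion_field <- function(matches, transform, pixel_size_pre = 1.0) {
  if (all(is.na(matches$inlier_mask))) stop("inlier_mask not set; run fit_similarity_ransac first")
  keep <- which(matches$inlier_mask)
  if (length(keep) == 0) stop("empty distortion field: no inliers")
  pa <- matches$points_a[keep, , drop = FALSE]
  pb <- matches$points_b[keep, , drop = FALSE]
  res <- (apply_transform(transform, pa) - pb) / transform$scale * pixel_size_pre
  structure(list(anchor_points = pa * pixel_size_pre, residual_vectors = res),
            class = "DistortionField")
}

#' @export
print.DistortionField <- function(x, ...) {
  m <- sqrt(rowSums(x$residual_vectors^2))
  cat(sprintf("DistortionField: %d anchors, |r| mean %.4g um, max %.4g um\n",
              nrow(x$anchor_points), mean(m), max(m)))
  invisible(x)
}

#' RMS length-measurement-error curve
#'
#' Any distance measured between two features inherits the error
#' `||v_i - v_j||` from their distortion vectors. Random anchor pairs are
#' sampled (seeded, capped at `n_pairs_max`), binned by their pre-expansion
#' separation, and summarized as the RMS error per measurement-length bin -
#' the standard expansion-microscopy distortion readout.
#'
#' @param field a [distortion_field()].
#' @param n_pairs_max maximum sampled pairs (default 1e5).
#' @param bin_width bin width in biological micrometres.
#' @param seed integer seed for pair sampling.
#' @return object of class `RMSCurve`: data.frame-like list with
#'   `length_bins` (bin centres, um), `rms_error` (um), `sem` (um),
#'   `n_pairs`.
#' @export
rms_error_curve <- function(field, n_pairs_max = 1e5, bin_width = 1.0, seed = 1) {
  n <- nrow(field$anchor_points)
  if (n < 2) stop("need at least 2 anchor points")
  n_all <- n * (n - 1) / 2
  with_seed(seed, {
    if (n_all <= n_pairs_max) {
      idx <- utils::combn(n, 2)
      i <- idx[1, ]; j <- idx[2, ]
    } else {
      i <- sample.int(n, n_pairs_max, replace = TRUE)
      j <- sample.int(n, n_pairs_max, replace = TRUE)
      ok <- i != j
      i <- i[ok]; j <- j[ok]
    }
  })
  dv <- field$residual_vectors[i, , drop = FALSE] -
    field$residual_vectors[j, , drop = FALSE]
  err <- sqrt(rowSums(dv^2))
  dp <- field$anchor_points[i, , drop = FALSE] -
    field$anchor_points[j, , drop = FALSE]
  len <- sqrt(rowSums(dp^2))
  bin <- floor(len / bin_width)
  ub <- sort(unique(bin))
  rms <- sem <- np <- numeric(length(ub))
  for (k in seq_along(ub)) {
    e <- err[bin == ub[k]]
    np[k] <- length(e)
    rms[k] <- sqrt(mean(e^2))
    sem[k] <- stats::sd(e) / sqrt(length(e))
  }
  structure(list(length_bins = (ub + 0.5) * bin_width, rms_error = rms,
                 sem = sem, n_pairs = np),
            class = "RMSCurve")
}

#' @export
print.RMSCurve <- function(x, ...) {
  cat(sprintf("RMSCurve: %d bins, RMS %.4g-%.4g um over lengths %.3g-%.3g um\n",
              length(x$length_bins), min(x$rms_error), max(x$rms_error),
              min(x$length_bins), max(x$length_bins)))
  invisible(x)
}

#' Percent distortion at the curve plateau
#'
#' Scalar distortion summary: `rms_error(L) / L` over the curve's plateau,
#' defined as the well-populated bins (>= `min_pairs` sampled pairs) in the
#' upper half of the measured length range, pooled with pair-count weights:
#' `100 * sqrt(sum(n * rms^2) / sum(n)) / (sum(n * L) / sum(n))`. Pooling
#' several bins stabilizes the scalar against sparse large-length bins. The
#' definition travels with the result since curve-to-scalar reduction is a
#' reporting choice.
#'
#' @param curve an [rms_error_curve()].
#' @param min_pairs minimum pair count for a bin to qualify.
#' @return percent distortion (numeric), with attributes `length_um` (the
#'   weighted plateau length) and `definition`.
#' @export
percent_distortion <- function(curve, min_pairs = 50L) {
  ok <- which(curve$n_pairs >= min_pairs)
  if (length(ok) == 0) ok <- which.max(curve$n_pairs)
  lmax <- max(curve$length_bins[ok])
  k <- ok[curve$length_bins[ok] >= lmax / 2]
  n <- curve$n_pairs[k]
  rms <- sqrt(sum(n * curve$rms_error[k]^2) / sum(n))
  lbar <- sum(n * curve$length_bins[k]) / sum(n)
  structure(100 * rms / lbar,
            length_um = lbar,
            definition = paste("100 * pooled rms / mean length over bins with >=",
                               min_pairs, "pairs in the upper half of the length range"))
}

#' Expansion-factor estimation
#'
#' All four estimation routes used in practice:
#' \describe{
#'   \item{`keypoint`}{from a fitted [similarity_transform()]: factor =
#'     `scale * pixel_size_post / pixel_size_pre`.}
#'   \item{`particle_area`}{threshold and binarize matched pre/post images of
#'     a particle suspension, label particles, and take the square root of
#'     the ratio of average post- to average pre-expansion particle area (in
#'     physical units).}
#'   \item{`length`}{ratio of mean manually-measured lengths (e.g. cell
#'     widths), post over pre.}
#'   \item{`tissue_size`}{ratio of two scalar sizes of the whole specimen.}
#' }
#'
#' @param pre,post method-specific inputs: `keypoint` ignores them (pass the
#'   transform in `params$transform`); `particle_area` takes 2D images;
#'   `length` takes numeric vectors of measured lengths; `tissue_size` takes
#'   two scalars.
#' @param method one of `"keypoint"`, `"particle_area"`, `"length"`,
#'   `"tissue_size"`.
#' @param params list of extras: `transform`, `pixel_size_pre`,
#'   `pixel_size_post` (default 1), `threshold` (`"otsu"` or numeric),
#'   `min_particle_px` (absolute size floor, default 5), `rel_min_frac`
#'   (relative floor as a fraction of the median particle size, default 0.1
#'   — scale-free rejection of noise specks).
#' @return object of class `ExpansionEstimate`: `factor`, `method`, `n`, `sd`.
#' @export
expansion_factor <- function(pre = NULL, post = NULL,
                             method = c("keypoint", "particle_area", "length",
                                        "tissue_size"),
                             params = list()) {
  method <- match.arg(method)
  psp <- params$pixel_size_pre %||% 1.0
  pso <- params$pixel_size_post %||% 1.0
  n <- NA_integer_; sd_ <- NA_real_
  if (method == "keypoint") {
    tr <- params$transform
    if (is.null(tr)) stop("keypoint method needs params$transform")
    factor <- tr$scale * pso / psp
  } else if (method == "particle_area") {
    areas <- function(img, psz) {
      thr <- params$threshold %||% "otsu"
      t_ <- if (identical(thr, "otsu")) otsu_threshold(img) else thr
      lab <- label_components(array(img > t_, c(1, dim(img))))
      sz <- lab$particle_sizes[lab$particle_sizes >= (params$min_particle_px %||% 5L)]
      if (length(sz) == 0) stop("segmentation error: no particles detected")
      # noise specks are tiny relative to real particles at any expansion
      # factor; a median-relative floor stays scale-free
      sz <- sz[sz >= (params$rel_min_frac %||% 0.1) * stats::median(sz)]
      sz * psz^2
    }
    a_pre <- areas(pre, psp); a_post <- areas(post, pso)
    factor <- sqrt(mean(a_post) / mean(a_pre))
    n <- min(length(a_pre), length(a_post))
  } else if (method == "length") {
    if (length(pre) < 1 || length(post) < 1) stop("need length samples")
    factor <- mean(post) / mean(pre)
    n <- min(length(pre), length(post))
    sd_ <- factor * sqrt(stats::var(post) / (length(post) * mean(post)^2) +
                           stats::var(pre) / (length(pre) * mean(pre)^2))
  } else {
    if (length(pre) != 1 || length(post) != 1) stop("tissue_size takes two scalars")
    factor <- post / pre
  }
  if (!is.finite(factor) || factor <= 0) stop("non-positive expansion factor")
  structure(list(factor = factor, method = method, n = n, sd = sd_),
            class = "ExpansionEstimate")
}

#' @export
print.ExpansionEstimate <- function(x, ...) {
  cat(sprintf("ExpansionEstimate: %.3f (%s method%s%s)\n", x$factor, x$method,
              if (!is.na(x$n)) paste0(", n=", x$n) else "",
              if (!is.na(x$sd)) sprintf(", sd=%.3f", x$sd) else ""))
  invisible(x)
}

#' Otsu threshold of a grayscale image
#'
#' Exact maximization of between-class variance over a 256-bin histogram.
#'
#' @param img numeric matrix/array.
#' @param n_bins histogram resolution.
#' @return threshold on the intensity scale of `img`.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.vector(img)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  b <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1L)
  h <- tabulate(b + 1L, n_bins)
  p <- h / sum(h)
  mids <- (seq_len(n_bins) - 0.5) / n_bins * (hi - lo) + lo
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Rescale stack metadata to biological scale
#'
#' Divides the pixel sizes by the estimated expansion factor so that
#' downstream measurements read in pre-expansion (biological) units; the
#' intensity data are untouched. Factors compose multiplicatively across
#' repeated calls.
#'
#' @param stack an [image_stack()].
#' @param estimate an [expansion_factor()] result (or a bare positive number).
#' @return the stack with `pixel_size_xy`, `pixel_size_z` divided by the
#'   factor and `expansion_factor` metadata updated.
#' @export
normalize_to_biological_scale <- function(stack, estimate) {
  stopifnot(inherits(stack, "ImageStack"))
  f <- if (inherits(estimate, "ExpansionEstimate")) estimate$factor else estimate
  if (!is.finite(f) || f <= 0) stop("expansion factor must be > 0")
  stack$pixel_size_xy <- stack$pixel_size_xy / f
  stack$pixel_size_z <- stack$pixel_size_z / f
  stack$expansion_factor <- if (is.na(stack$expansion_factor)) f
    else stack$expansion_factor * f
  stack
}
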