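#' Find the post-expansion z projection best matching a pre-expansion plane
#'
#' A single pre-expansion plane corresponds, after expansion, to a slab of
#' post-expansion planes; which slab (and how thick) depends on the expansion
#' factor and imaging conditions. All contiguous z-windows with lengths in
#' `window_lengths` are max-projected, keypoint-matched to the pre image and
#' consensus-filtered; the window with the most inliers wins.
#'
#' @param pre_img 2D pre-expansion image.
#' @param post_stack post-expansion [image_stack()].
#' @param window_lengths candidate window lengths in planes (default 5:30,
#'   clipped to the stack depth; a depth-1 stack degenerates to direct
#'   matching).
#' @param channel 0-based channel of `post_stack`.
#' @param stride start-plane stride for the window search.
#' @param inlier_tol,seed passed to [fit_similarity_ransac()].
#' @param ... passed to [detect_and_match_keypoints()].
#' @return list `z_window` (half-open 0-based `c(start, stop)`), `projection`,
#'   `matches` (inlier mask set), `transform`, `n_inliers`.
#' @export
find_best_z_projection <- function(pre_img, post_stack, window_lengths = 5:30,
                                   channel = 0L, stride = 1L,
                                   inlier_tol = 3, seed = 1, ...) {
  stopifnot(inherits(post_stack, "ImageStack"))
  nz <- dim(post_stack$data)[2]
  lens <- unique(pmin(window_lengths, nz))
  lens <- lens[lens >= 1L]
  if (length(lens) == 0) stop("no feasible window length for depth ", nz)
  best <- NULL
  for (len in lens) {
    starts <- seq(0L, nz - len, by = stride)
    for (s in starts) {
      proj <- max_project(post_stack, channel = channel, z_window = c(s, s + len))
      fit <- tryCatch({
        m <- detect_and_match_keypoints(pre_img, proj, ...)
        fit_similarity_ransac(m, inlier_tol = inlier_tol, seed = seed)
      }, error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$n_inliers > best$n_inliers)
        best <- list(z_window = c(s, s + len), projection = proj,
                     matches = fit$matches, transform = fit$transform,
                     n_inliers = fit$n_inliers)
    }
  }
  if (is.null(best) || best$n_inliers < 4L)
    stop("pairing failure: no z window produced >= 4 consensus matches")
  best
}

#' Per-pixel displacement field
#'
#' Dense non-rigid correction defined on the fixed-image grid: the moving
#' image resampled at `x + field(x)` matches the fixed image, so the same
#' field transfers directly to every other channel acquired in the same
#' round.
#'
#' @param dy,dx matrices of `(dy, dx)` displacements in pixels.
#' @return object of class `DisplacementField`.
#' @export
displacement_field <- function(dy, dx) {
  stopifnot(all(dim(dy) == dim(dx)))
  if (any(!is.finite(dy)) || any(!is.finite(dx)))
    stop("displacement field must be finite")
  structure(list(dy = dy, dx = dx), class = "DisplacementField")
}

#' @export
print.DisplacementField <- function(x, ...) {
  m <- sqrt(x$dy^2 + x$dx^2)
  cat(sprintf("DisplacementField: %d x %d px, |d| mean %.3g, max %.3g px\n",
              nrow(x$dy), ncol(x$dy), mean(m), max(m)))
  invisible(x)
}

#' Warp an image by a displacement field
#'
#' Samples `img` at `x + field(x)` by bilinear interpolation (border clamp).
#'
#' @param img 2D matrix (the moving image, fixed-grid sized).
#' @param field a [displacement_field()].
#' @return warped matrix.
#' @export
warp_image <- function(img, field) {
  ny <- nrow(img); nx <- ncol(img)
  gy <- matrix(0:(ny - 1), ny, nx)
  gx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  out <- interp2(img, gy + field$dy, gx + field$dx)
  matrix(out, ny, nx)
}

# Compose: new_field(x) = u(x) + v(x + u(x)) (apply u first, then v).
.compose_fields <- function(v, u) {
  ny <- nrow(v$dy); nx <- ncol(v$dy)
  gy <- matrix(0:(ny - 1), ny, nx)
  gx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  displacement_field(
    u$dy + matrix(interp2(v$dy, gy + u$dy, gx + u$dx), ny, nx),
    u$dx + matrix(interp2(v$dx, gy + u$dy, gx + u$dx), ny, nx))
}

#' Diffeomorphic demons refinement
#'
#' Iterative intensity-driven non-rigid registration for the minor local
#' misalignment left after rigid alignment: each iteration computes the
#' classic demons force from the intensity difference and the fixed-image
#' gradient, Gaussian-smooths the incremental field (fluid regularization),
#' composes it with the running field (keeping the total deformation a
#' composition of small smooth steps), and lightly smooths the total
#' (diffusion regularization). Stops early with a warning if the residual
#' increases three iterations running. 3D inputs are registered plane by
#' plane.
#'
#' @param moving,fixed same-shape 2D matrices or 3D `(z, y, x)` arrays,
#'   already rigidly aligned.
#' @param n_iter maximum iterations.
#' @param smoothing_sigma fluid regularization sigma, px.
#' @param diffusion_sigma total-field smoothing sigma, px (0 disables).
#' @return for 2D input a [displacement_field()] with attributes
#'   `"residuals"` (per-iteration MSE, element 1 = before any update) and
#'   `"converged"`; for 3D input a list of per-plane fields.
#' @export
demons_refine <- function(moving, fixed, n_iter = 60L, smoothing_sigma = 2,
                          diffusion_sigma = 0.5) {
  if (length(dim(moving) %||% dim(as.matrix(moving))) == 2 && !is.matrix(moving))
    moving <- as.matrix(moving)
  if (!all((dim(moving) %||% length(moving)) == (dim(fixed) %||% length(fixed))))
    stop("moving and fixed must have the same shape")
  if (length(dim(moving)) == 3) {
    return(lapply(seq_len(dim(moving)[1]), function(z)
      demons_refine(moving[z, , ], fixed[z, , ], n_iter = n_iter,
                    smoothing_sigma = smoothing_sigma,
                    diffusion_sigma = diffusion_sigma)))
  }
  ny <- nrow(fixed); nx <- ncol(fixed)
  grad <- function(img) {
    gy <- img; gx <- img
    gy[2:(ny - 1), ] <- (img[3:ny, ] - img[1:(ny - 2), ]) / 2
    gy[1, ] <- img[2, ] - img[1, ]; gy[ny, ] <- img[ny, ] - img[ny - 1, ]
    gx[, 2:(nx - 1)] <- (img[, 3:nx] - img[, 1:(nx - 2)]) / 2
    gx[, 1] <- img[, 2] - img[, 1]; gx[, nx] <- img[, nx] - img[, nx - 1]
    list(gy = gy, gx = gx)
  }
  gf <- grad(fixed)
  fld <- displacement_field(matrix(0, ny, nx), matrix(0, ny, nx))
  mw <- moving
  resids <- mean((mw - fixed)^2)
  best <- fld; best_res <- resids[1]
  rising <- 0L; converged <- TRUE
  for (it in seq_len(n_iter)) {
    diffi <- mw - fixed
    den <- gf$gy^2 + gf$gx^2 + diffi^2
    # suppress noise-driven forces: in flat, well-aligned regions the
    # residual is pure noise and the raw demons force is O(1) there. The
    # noise level is estimated from the high-frequency part of the residual
    # (misalignment is spatially smooth, sensor noise is not).
    sig <- stats::mad(diffi - gauss_blur(diffi, 1), center = 0)
    ok <- den > 1e-9 & abs(diffi) > 3 * sig
    uy <- matrix(0, ny, nx); ux <- matrix(0, ny, nx)
    uy[ok] <- -diffi[ok] * gf$gy[ok] / den[ok]
    ux[ok] <- -diffi[ok] * gf$gx[ok] / den[ok]
    uy <- gauss_blur(uy, smoothing_sigma)
    ux <- gauss_blur(ux, smoothing_sigma)
    fld <- .compose_fields(fld, displacement_field(uy, ux))
    if (diffusion_sigma > 0)
      fld <- displacement_field(gauss_blur(fld$dy, diffusion_sigma),
                                gauss_blur(fld$dx, diffusion_sigma))
    mw <- warp_image(moving, fld)
    r <- mean((mw - fixed)^2)
    prev <- resids[length(resids)]
    resids <- c(resids, r)
    if (abs(r - prev) <= 1e-14 * max(prev, 1)) break   # plateau: converged
    if (r < best_res) { best_res <- r; best <- fld; rising <- 0L }
    else if (r > prev) {
      rising <- rising + 1L
      if (rising >= 3L) {
        warning("demons diverged (residual rose 3 iterations running); ",
                "returning best field after ", it, " iterations")
        converged <- FALSE
        break
      }
    }
  }
  attr(best, "residuals") <- resids
  attr(best, "converged") <- converged
  best
}

# Resample one 2D image under a similarity transform mapping moving -> fixed
# coordinates: out(x_fixed) = moving(T^{-1}(x_fixed)).
.resample_similarity <- function(img, transform) {
  ny <- nrow(img); nx <- ncol(img)
  inv <- invert_transform(transform)
  gy <- matrix(0:(ny - 1), ny, nx)
  gx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  p <- apply_transform(inv, cbind(as.vector(gy), as.vector(gx)))
  matrix(interp2(img, p[, 1], p[, 2]), ny, nx)
}

#' Register a multi-round series to its first round
#'
#' Multi-round alignment on the nuclear reference channel: consecutive
#' rounds are keypoint-matched on the reference channel and fitted with a
#' rigid model (similarity with scale locked to 1 - no expansion happens
#' between rounds), composed back to round 1, and optionally refined with
#' [demons_refine()]. Every transform estimated on the reference channel is
#' applied to all channels of its round.
#'
#' @param series a `RoundSeries` (see [gen_round_series()]).
#' @param demons run the non-rigid refinement after the rigid stage.
#' @param demons_iter,smoothing_sigma passed to [demons_refine()].
#' @param inlier_tol,seed passed to [fit_similarity_ransac()].
#' @return the series with all rounds resampled into the round-1 frame;
#'   per-round transforms attached as attribute `"transforms"` and demons
#'   fields (per round, per plane) as `"fields"`.
#' @export
register_rounds <- function(series, demons = TRUE, demons_iter = 30L,
                            smoothing_sigma = 2, inlier_tol = 3, seed = 1) {
  stopifnot(inherits(series, "RoundSeries"))
  ref_idx <- match(series$reference_channel, series$rounds[[1]]$channel_names)
  if (is.na(ref_idx)) stop("reference channel '", series$reference_channel,
                           "' not found")
  n_rounds <- length(series$rounds)
  transforms <- vector("list", n_rounds)
  fields <- vector("list", n_rounds)
  transforms[[1]] <- similarity_transform()
  ref1_proj <- max_project(series$rounds[[1]], channel = ref_idx - 1L)
  acc <- similarity_transform()
  for (i in seq_len(n_rounds)[-1]) {
    proj_i <- max_project(series$rounds[[i]], channel = ref_idx - 1L)
    m <- detect_and_match_keypoints(ref1_proj, proj_i,
                                    sigma_range_b = c(1.5, 12))
    # transform maps round-i coords -> round-1 coords, so fit b -> a
    fit <- fit_similarity_ransac(match_set(m$points_b, m$points_a, m$scores),
                                 inlier_tol = inlier_tol, seed = seed,
                                 lock_scale = TRUE)
    # keypoint localization noise leaves ~0.05 px translation error; refine
    # on the reference projection by phase correlation
    aligned <- .resample_similarity(proj_i, fit$transform)
    d <- estimate_shift(ref1_proj, aligned)
    fit$transform$translation <- fit$transform$translation - d
    transforms[[i]] <- fit$transform
    st <- series$rounds[[i]]
    d <- dim(st$data)
    for (ch in seq_len(d[1])) for (z in seq_len(d[2]))
      st$data[ch, z, , ] <- .resample_similarity(st$data[ch, z, , ],
                                                 fit$transform)
    if (demons) {
      d <- dim(st$data)
      flds <- vector("list", d[2])
      for (z in seq_len(d[2])) {
        f <- demons_refine(st$data[ref_idx, z, , ],
                           series$rounds[[1]]$data[ref_idx, z, , ],
                           n_iter = demons_iter,
                           smoothing_sigma = smoothing_sigma)
        flds[[z]] <- f
        for (ch in seq_len(d[1]))
          st$data[ch, z, , ] <- warp_image(st$data[ch, z, , ], f)
      }
      fields[[i]] <- flds
    }
    series$rounds[[i]] <- st
  }
  attr(series, "transforms") <- transforms
  attr(series, "fields") <- fields
  series
}
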