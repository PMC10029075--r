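# Seeded synthetic-data generators with exact ground truth for every pipeline
# stage. These stand in for raw microscopy stacks: Gaussian-blob fields for
# keypoint work (blobs get random intensity and slight anisotropy so that
# descriptors have texture), cumulative staining rounds obeying the recursive
# carry-over model, raster-interval label volumes with exact overlap counts,
# and two-state blinking-emitter movies for fluctuation imaging.

.rand_blobs <- function(n, ny, nx, margin, sigma_range = c(2, 3),
                        min_separation = 0) {
  centers <- cbind(stats::runif(n, margin, ny - 1 - margin),
                   stats::runif(n, margin, nx - 1 - margin))
  if (min_separation > 0) {
    kept <- 1L
    tries <- 0L
    while (length(kept) < n && tries < 200L * n) {
      cand <- c(stats::runif(1, margin, ny - 1 - margin),
                stats::runif(1, margin, nx - 1 - margin))
      d2 <- (centers[kept, 1] - cand[1])^2 + (centers[kept, 2] - cand[2])^2
      if (all(d2 >= min_separation^2)) {
        kept <- c(kept, length(kept) + 1L)
        centers[length(kept), ] <- cand
      }
      tries <- tries + 1L
    }
    n <- length(kept)
    centers <- centers[seq_len(n), , drop = FALSE]
  }
  list(centers = centers,
       sigma = stats::runif(n, sigma_range[1], sigma_range[2]),
       aniso = stats::runif(n, 0.78, 1.28),
       theta = stats::runif(n, 0, pi),
       amps = stats::runif(n, 0.45, 1))
}

#' Generate a synthetic pre/post-expansion image pair
#'
#' Emulates a validation field of view: the pre-expansion image holds
#' randomly placed Gaussian blobs; the post-expansion stack is the similarity
#' transform (uniform scale + rotation + translation) of the same scene into
#' a larger frame, optionally perturbed by a smooth non-rigid warp, rendered
#' into a small z-stack with Poisson + Gaussian noise. Exact blob-centre
#' correspondences are recorded as ground truth.
#'
#' @param n_objects number of blobs.
#' @param scale true linear expansion factor (> 0; physically 1-12).
#' @param rotation radians.
#' @param translation `(ty, tx)` pixels added after scaling/rotation about the
#'   frame centres.
#' @param warp_amplitude maximum displacement (px) of the added smooth
#'   zero-mean non-rigid field; 0 disables it.
#' @param noise_sd Gaussian read-noise sd (intensity units).
#' @param seed integer seed; same seed, same output.
#' @param pre_size `(ny, nx)` of the pre image.
#' @param n_z planes in the post stack; blob content sits in the middle third.
#' @param photons Poisson scale (photons per unit intensity); `Inf` disables
#'   shot noise.
#' @param pixel_size_xy physical pixel size (um) of both images.
#' @param min_separation minimum blob-centre distance in pre pixels (0 =
#'   unconstrained). Use > ~5 sigma to emulate a dispersed particle
#'   suspension, the regime of the particle-area expansion estimate.
#' @return list with `pre` (matrix), `post` ([image_stack()]), and `truth`:
#'   `scale`, `rotation`, `translation`, `warp_amplitude`, `transform` (the
#'   absolute [similarity_transform()] mapping pre to post pixel coords),
#'   `keypoint_truth` (data.frame `pre_y, pre_x, post_y, post_x`), and
#'   `z_content` (0-based plane range holding the scene).
#' @export
gen_expansion_pair <- function(n_objects = 40, scale = 4, rotation = 0,
                               translation = c(0, 0), warp_amplitude = 0,
                               noise_sd = 0.01, seed = 1,
                               pre_size = c(128, 128), n_z = 12L,
                               photons = 300, pixel_size_xy = 1.0,
                               min_separation = 0) {
  if (scale <= 0) stop("scale must be > 0")
  if (warp_amplitude < 0) stop("warp_amplitude must be >= 0")
  with_seed(seed, {
    ny <- pre_size[1]; nx <- pre_size[2]
    b <- .rand_blobs(n_objects, ny, nx, margin = 12,
                     min_separation = min_separation)
    n_objects <- nrow(b$centers)
    pre_clean <- render_blobs(ny, nx, b$centers,
                              cbind(b$sigma * b$aniso, b$sigma / b$aniso),
                              b$theta, b$amps)
    pre <- pmax(pre_clean + stats::rnorm(length(pre_clean), 0, noise_sd), 0)
    dim(pre) <- dim(pre_clean)

    pad <- 14
    pny <- ceiling(scale * ny) + 2 * pad
    pnx <- ceiling(scale * nx) + 2 * pad
    c0 <- c((ny - 1) / 2, (nx - 1) / 2)
    c1 <- c((pny - 1) / 2, (pnx - 1) / 2)
    ct <- cos(rotation); st <- sin(rotation)
    t_abs <- c1 + translation -
      scale * c(ct * c0[1] - st * c0[2], st * c0[1] + ct * c0[2])
    tr <- similarity_transform(scale, rotation, t_abs)

    q <- apply_transform(tr, b$centers)
    if (warp_amplitude > 0) {
      wf <- smooth_random_field(pny, pnx, warp_amplitude)
      q <- q + cbind(interp2(wf$dy, q[, 1], q[, 2]),
                     interp2(wf$dx, q[, 1], q[, 2]))
    }

    zc_lo <- floor(n_z / 3); zc_hi <- ceiling(2 * n_z / 3) - 1
    zc <- stats::runif(n_objects, zc_lo, zc_hi)
    sigma_z <- 2.0
    post <- array(0, c(1L, n_z, pny, pnx))
    for (z in seq_len(n_z) - 1L) {
      wz <- exp(-0.5 * (z - zc)^2 / sigma_z^2)
      keep <- wz > 1e-3
      if (!any(keep)) next
      post[1, z + 1L, , ] <- render_blobs(
        pny, pnx, q[keep, , drop = FALSE],
        cbind(b$sigma * b$aniso, b$sigma / b$aniso)[keep, , drop = FALSE] * scale,
        b$theta[keep], (b$amps * wz)[keep])
    }
    if (is.finite(photons))
      post <- array(stats::rpois(length(post), post * photons) / photons, dim(post))
    if (noise_sd > 0)
      post <- post + array(stats::rnorm(length(post), 0, noise_sd), dim(post))
    post <- pmax(post, 0)

    truth <- list(scale = scale, rotation = rotation, translation = translation,
                  warp_amplitude = warp_amplitude, transform = tr,
                  keypoint_truth = data.frame(pre_y = b$centers[, 1],
                                              pre_x = b$centers[, 2],
                                              post_y = q[, 1], post_x = q[, 2]),
                  z_content = c(zc_lo, zc_hi))
    list(pre = pre,
         post = image_stack(post, pixel_size_xy = pixel_size_xy,
                            pixel_size_z = 1.0, channel_names = "post"),
         truth = truth)
  })
}

# Raster-interval mask construction: channel regions are consecutive index
# intervals along the raster order (x fastest, then y, then z) of a shared
# sub-box, so every region is one 6-connected component and every pairwise
# intersection is an exact interval intersection.
.interval_masks <- function(shape, volumes, overlaps_vox, seed, margin = 8L) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  C <- length(volumes)
  starts <- integer(C); starts[1] <- 0L
  if (C > 1) for (i in 2:C) starts[i] <- starts[i - 1] + volumes[i - 1] - overlaps_vox[i - 1]
  if (any(starts < 0)) stop("infeasible geometry: overlap exceeds volume")
  total <- max(starts + volumes)
  a_need <- ceiling(total / nz)
  bx <- min(nx, max(4L, ceiling(sqrt(a_need))))
  by <- min(ny, max(4L, ceiling(a_need / bx)))
  if (by * bx * nz < total)
    stop("infeasible geometry: requested volumes do not fit in shape")
  bz <- ceiling(total / (by * bx))
  # keep regions away from the lateral frame edges (stage offsets between
  # rounds must not carry content out of view)
  my <- if (ny - by > 2L * margin) margin else 0L
  mx <- if (nx - bx > 2L * margin) margin else 0L
  with_seed(seed, {
    oz <- sample.int(nz - bz + 1L, 1L) - 1L
    oy <- my + sample.int(ny - by - 2L * my + 1L, 1L) - 1L
    ox <- mx + sample.int(nx - bx - 2L * mx + 1L, 1L) - 1L
  })
  masks <- vector("list", C)
  for (i in seq_len(C)) {
    m <- array(FALSE, shape)
    idx <- starts[i]:(starts[i] + volumes[i] - 1L)   # raster index in sub-box
    x <- idx %% bx; y <- (idx %/% bx) %% by; z <- idx %/% (bx * by)
    m[cbind(oz + z + 1L, oy + y + 1L, ox + x + 1L)] <- TRUE
    masks[[i]] <- m
  }
  masks
}

#' Generate two 3D label volumes with an exact overlap
#'
#' Builds two binary volumes whose intersection contains exactly
#' `round(overlap_fraction * min(volumes))` voxels, each volume a single
#' connected component, for ground-truthing volume-overlap colocalization.
#'
#' @param shape `(z, y, x)` volume dimensions.
#' @param volumes `c(volA, volB)` voxel counts.
#' @param overlap_fraction in `[0, 1]`, fraction of the smaller volume shared.
#' @param seed integer seed (placement only; counts are exact regardless).
#' @return list `mask_a`, `mask_b` (logical arrays) and `truth` with
#'   `overlap_voxels`, `frac_in_a`, `frac_in_b`.
#' @export
gen_label_volumes <- function(shape, volumes = c(1000, 500),
                              overlap_fraction = 0.5, seed = 1) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in [0, 1]")
  ov <- as.integer(round(overlap_fraction * min(volumes)))
  masks <- .interval_masks(shape, as.integer(volumes), ov, seed)
  o <- sum(masks[[1]] & masks[[2]])
  list(mask_a = masks[[1]], mask_b = masks[[2]],
       truth = list(overlap_voxels = o,
                    frac_in_a = o / volumes[1], frac_in_b = o / volumes[2]))
}

#' Generate a chain of label volumes with controlled pairwise overlaps
#'
#' Multi-channel extension of [gen_label_volumes()]: channel `i` overlaps
#' channel `i+1` by `overlaps[i]` of the smaller of the two volumes;
#' the full pairwise truth matrix is counted exactly from the masks.
#'
#' @param shape `(z, y, x)`.
#' @param volumes per-channel voxel counts.
#' @param overlaps length `C-1` fractions in `[0, 1]`.
#' @param seed integer seed.
#' @return list `masks` (list of logical arrays) and `truth_matrix`
#'   (`C x C` percentages, entry `(i, j)` = 100 * |i intersect j| / |i|).
#' @export
gen_coloc_volumes <- function(shape, volumes, overlaps, seed = 1) {
  C <- length(volumes)
  stopifnot(length(overlaps) == C - 1, all(overlaps >= 0 & overlaps <= 1))
  ov <- integer(C - 1)
  for (i in seq_len(C - 1))
    ov[i] <- as.integer(round(overlaps[i] * min(volumes[i], volumes[i + 1])))
  masks <- .interval_masks(shape, as.integer(volumes), ov, seed)
  tm <- matrix(0, C, C)
  for (i in seq_len(C)) for (j in seq_len(C))
    tm[i, j] <- 100 * sum(masks[[i]] & masks[[j]]) / sum(masks[[i]])
  list(masks = masks, truth_matrix = tm)
}

# Translate an image by (dy, dx) sampling bilinearly, filling the vacated
# border with `fill` instead of wrapping.
.shift_fill <- function(img, dy, dx, fill = 0) {
  ny <- nrow(img); nx <- ncol(img)
  gy <- matrix(0:(ny - 1), ny, nx) - dy
  gx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE) - dx
  out <- matrix(interp2(img, gy, gx), ny, nx)
  out[gy < 0 | gy > ny - 1 | gx < 0 | gx > nx - 1] <- fill
  out
}

#' Generate a cumulative-staining round series
#'
#' Simulates sequential staining-and-imaging cycles in which signal
#' accumulates: round 1 observes its own true signal, and each later round
#' observes its true signal plus `alpha` times the previous *observed*
#' (accumulated) round, per channel. A shared nuclear reference channel
#' ("DAPI") is re-stained identically every round and carries nothing over.
#' Each round is then rigidly offset and noised, emulating stage error
#' between cycles.
#'
#' @param n_rounds number of staining/imaging cycles (default 3, the study
#'   regime).
#' @param n_channels detection channels per round including the reference
#'   (default 4: DAPI + 3 markers, giving 10 distinct colors over 3 rounds).
#' @param alpha_per_round carry-over coefficients: vector of length
#'   `n_rounds - 1` (shared by all marker channels) or matrix
#'   `(n_channels - 1) x (n_rounds - 1)`.
#' @param offsets matrix `n_rounds x 2` of `(dy, dx)` rigid offsets applied to
#'   each round (row 1 normally zero).
#' @param noise_sd Gaussian noise sd added to every observed image.
#' @param background constant offset added to every observed image (camera
#'   baseline; keeps adaptive thresholding well-posed downstream).
#' @param shape `(z, y, x)`; z = 1 gives planar rounds.
#' @param signal `"blobs"` for random marker blob fields, `"volumes"` for
#'   solid marker volumes with controlled pairwise overlaps (3D end-to-end
#'   colocalization truth).
#' @param overlaps passed to [gen_coloc_volumes()] when `signal = "volumes"`:
#'   length `n_markers - 1` chain-overlap fractions (default 0.4).
#' @param marker_volume voxels per marker volume in `"volumes"` mode.
#' @param seed integer seed.
#' @return list with `series` (class `RoundSeries`: `rounds` = list of
#'   [image_stack()], `reference_channel = "DAPI"`) and `truth`:
#'   `alpha_per_round` (matrix), `true_images` (`[[round]][[channel]]`
#'   arrays, unshifted frame), `registration_offsets`, `marker_names`, and in
#'   volumes mode `coloc_truth` (pct matrix over markers) and `masks`.
#' @export
gen_round_series <- function(n_rounds = 3L, n_channels = 4L,
                             alpha_per_round = c(0.3, 0.6),
                             offsets = NULL, noise_sd = 0.005,
                             background = 0.1,
                             shape = c(1L, 128L, 128L),
                             signal = c("blobs", "volumes"),
                             overlaps = NULL, marker_volume = 900L, seed = 1) {
  signal <- match.arg(signal)
  if (n_rounds < 2L) stop("need n_rounds >= 2")
  n_mark <- n_channels - 1L
  A <- alpha_per_round
  if (is.null(dim(A))) A <- matrix(rep(A, each = n_mark), n_mark, n_rounds - 1L)
  if (any(A < 0)) stop("carry-over alpha must be >= 0")
  if (!all(dim(A) == c(n_mark, n_rounds - 1L)))
    stop("alpha_per_round must have length n_rounds-1 or dim (n_channels-1) x (n_rounds-1)")
  if (is.null(offsets)) offsets <- matrix(0, n_rounds, 2)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  marker_names <- paste0("R", rep(seq_len(n_rounds), each = n_mark),
                         "_ch", rep(seq_len(n_mark), n_rounds))

  coloc_truth <- NULL; masks <- NULL
  truth_imgs <- vector("list", n_rounds)
  with_seed(seed, {
    # reference channel: nuclear blob field, identical every round
    bref <- .rand_blobs(18, ny, nx, margin = 10, sigma_range = c(3, 5))
    dapi2d <- render_blobs(ny, nx, bref$centers,
                           cbind(bref$sigma * bref$aniso, bref$sigma / bref$aniso),
                           bref$theta, bref$amps)
    dapi <- array(rep(dapi2d, each = 1), c(nz, ny, nx))
    if (nz > 1) for (z in seq_len(nz)) dapi[z, , ] <- dapi2d *
        exp(-0.5 * ((z - (nz + 1) / 2) / (nz / 3))^2)

    if (signal == "volumes") {
      n_tot <- n_mark * n_rounds
      if (is.null(overlaps)) overlaps <- rep(0.4, n_tot - 1L)
      cv <- gen_coloc_volumes(shape, rep(marker_volume, n_tot), overlaps,
                              seed = seed + 1L)
      masks <- cv$masks; coloc_truth <- cv$truth_matrix
    }
    k <- 0L
    for (i in seq_len(n_rounds)) {
      truth_imgs[[i]] <- vector("list", n_channels)
      truth_imgs[[i]][[1]] <- dapi
      for (c in seq_len(n_mark)) {
        k <- k + 1L
        if (signal == "volumes") {
          truth_imgs[[i]][[c + 1L]] <- array(as.numeric(masks[[k]]), shape)
        } else {
          bm <- .rand_blobs(25, ny, nx, margin = 8)
          f2d <- render_blobs(ny, nx, bm$centers,
                              cbind(bm$sigma * bm$aniso, bm$sigma / bm$aniso),
                              bm$theta, bm$amps)
          truth_imgs[[i]][[c + 1L]] <- array(rep(f2d, nz), c(nz, ny, nx))
        }
      }
    }

    rounds <- vector("list", n_rounds)
    prev_obs <- NULL
    for (i in seq_len(n_rounds)) {
      obs <- array(0, c(n_channels, nz, ny, nx))
      obs[1, , , ] <- dapi
      for (c in seq_len(n_mark)) {
        v <- truth_imgs[[i]][[c + 1L]]
        if (i > 1L) v <- v + A[c, i - 1L] * array(prev_obs[c + 1L, , , ], shape)
        obs[c + 1L, , , ] <- v
      }
      prev_obs <- obs   # accumulation happens before offset/noise
      out <- obs + background
      if (any(offsets[i, ] != 0)) {
        # stage offset: content is translated and the vacated strip images as
        # bare background (no periodic wrap)
        for (ch in seq_len(n_channels)) for (z in seq_len(nz))
          out[ch, z, , ] <- .shift_fill(out[ch, z, , ],
                                        offsets[i, 1], offsets[i, 2],
                                        fill = background)
      }
      if (noise_sd > 0)
        out <- out + array(stats::rnorm(length(out), 0, noise_sd), dim(out))
      rounds[[i]] <- image_stack(pmax(out, 0), pixel_size_xy = 1.0,
                                 pixel_size_z = if (nz > 1) 1.0 else NULL,
                                 channel_names = c("DAPI", paste0("ch", seq_len(n_mark))))
    }
    series <- structure(list(rounds = rounds, reference_channel = "DAPI"),
                        class = "RoundSeries")
    list(series = series,
         truth = list(alpha_per_round = A, true_images = truth_imgs,
                      registration_offsets = offsets,
                      marker_names = marker_names,
                      coloc_truth = coloc_truth, masks = masks,
                      background = background))
  })
}

#' @export
print.RoundSeries <- function(x, ...) {
  cat(sprintf("RoundSeries: %d rounds, reference channel '%s'\n",
              length(x$rounds), x$reference_channel))
  invisible(x)
}

#' Ground-truth description of blinking emitters
#'
#' @param positions matrix `[n, 2]` of `(y, x)` subpixel emitter positions.
#' @param p_on per-frame probability of switching off -> on.
#' @param p_off per-frame probability of switching on -> off.
#' @param psf_sigma Gaussian PSF sigma, pixels.
#' @param photon_rate photons per frame emitted while on.
#' @return an object of class `EmitterTruth`.
#' @export
emitter_truth <- function(positions, p_on = 0.3, p_off = 0.5,
                          psf_sigma = 1.8, photon_rate = 800) {
  positions <- rbind(positions)
  if (p_on < 0 || p_on > 1 || p_off < 0 || p_off > 1)
    stop("switching probabilities must be in [0, 1]")
  if (psf_sigma <= 0) stop("psf_sigma must be > 0")
  structure(list(positions = positions, p_on = p_on, p_off = p_off,
                 psf_sigma = psf_sigma, photon_rate = photon_rate),
            class = "EmitterTruth")
}

#' Generate a blinking-emitter movie
#'
#' Renders stochastically blinking point emitters: each emitter follows an
#' independent two-state Markov chain (started at its stationary
#' distribution), on-emitters contribute a Gaussian PSF of total flux
#' `photon_rate`, and every frame is Poisson-sampled on top of a constant
#' background. This is the input regime for fluctuation (SOFI) imaging,
#' typically recorded as 50-100 frames per z-plane.
#'
#' @param truth an [emitter_truth()].
#' @param n_frames frames to simulate (>= 2; 50-100 is the intended regime).
#' @param background photons per pixel per frame.
#' @param shape `(ny, nx)` frame size.
#' @param seed integer seed.
#' @param frame_interval seconds per frame.
#' @return a [movie()]; the realized on/off state matrix `(t x n_emitters)`
#'   is attached as attribute `"states"`.
#' @export
gen_blinking_movie <- function(truth, n_frames = 100L, background = 2,
                               shape = c(64L, 64L), seed = 1,
                               frame_interval = 0.1) {
  stopifnot(inherits(truth, "EmitterTruth"))
  if (n_frames < 2L) stop("need n_frames >= 2")
  n_em <- nrow(truth$positions)
  ny <- shape[1]; nx <- shape[2]
  with_seed(seed, {
    p_stat <- if (truth$p_on + truth$p_off > 0)
      truth$p_on / (truth$p_on + truth$p_off) else 1
    states <- matrix(FALSE, n_frames, n_em)
    states[1, ] <- stats::runif(n_em) < p_stat
    if (n_frames > 1) for (t in 2:n_frames) {
      u <- stats::runif(n_em)
      states[t, ] <- ifelse(states[t - 1, ], u >= truth$p_off, u < truth$p_on)
    }
    amp <- truth$photon_rate / (2 * pi * truth$psf_sigma^2)
    psf_imgs <- lapply(seq_len(n_em), function(i)
      render_blobs(ny, nx, truth$positions[i, , drop = FALSE],
                   cbind(truth$psf_sigma, truth$psf_sigma), 0, amp))
    frames <- array(0, c(n_frames, ny, nx))
    for (t in seq_len(n_frames)) {
      lam <- matrix(background, ny, nx)
      on <- which(states[t, ])
      for (i in on) lam <- lam + psf_imgs[[i]]
      frames[t, , ] <- stats::rpois(length(lam), lam)
    }
    mv <- movie(frames, frame_interval = frame_interval, pixel_size_xy = 1.0)
    attr(mv, "states") <- states
    mv
  })
}
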