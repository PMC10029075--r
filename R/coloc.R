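#' Label the 26-connected components of a 3D mask
#'
#' Voxels sharing a face, edge or corner belong to the same particle.
#' Components smaller than `min_size` voxels are removed and the surviving
#' labels renumbered contiguously.
#'
#' @param mask logical 3D array `(z, y, x)` (a 2D matrix is treated as a
#'   single-plane volume, where 26-connectivity reduces to 8-connectivity).
#' @param min_size minimum particle volume in voxels.
#' @return object of class `LabelVolume`: `labels` (integer array, 0 =
#'   background), `n_particles`, `particle_sizes`.
#' @export
label_components <- function(mask, min_size = 1L) {
  if (is.matrix(mask)) mask <- array(mask, c(1L, dim(mask)))
  stopifnot(length(dim(mask)) == 3)
  d <- dim(mask)
  lab <- .label3d_cc(as.logical(mask), d[1], d[2], d[3])
  sizes <- if (max(lab) > 0) tabulate(lab, max(lab)) else integer(0)
  if (min_size > 1L && length(sizes) > 0) {
    keep <- which(sizes >= min_size)
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    lab <- ifelse(lab > 0L, remap[pmax(lab, 1L)], 0L)
    sizes <- sizes[keep]
  }
  dim(lab) <- d
  structure(list(labels = lab, n_particles = length(sizes),
                 particle_sizes = as.integer(sizes)),
            class = "LabelVolume")
}

#' @export
print.LabelVolume <- function(x, ...) {
  cat(sprintf("LabelVolume: %d particle(s), %d foreground voxels\n",
              x$n_particles, sum(x$particle_sizes)))
  invisible(x)
}

#' Adaptive local thresholding and particle labeling
#'
#' A voxel is foreground iff its value exceeds the local mean over a cubic
#' window scaled by `1 + (1 - sensitivity)`: sensitivity 1 accepts anything
#' above the local mean, lower values demand a proportionally brighter
#' voxel, which is how per-channel signal-to-noise differences are absorbed.
#' Foreground is labeled by 26-connectivity and particles below `min_size`
#' voxels are dropped. An all-background result is a valid empty volume,
#' not an error.
#'
#' @param volume numeric 3D array `(z, y, x)` (2D allowed).
#' @param sensitivity in `[0, 1]`; default 0.5.
#' @param window odd cubic window edge in voxels (>= 3); shrinks at borders.
#' @param min_size minimum particle volume, voxels (default 27 = 3^3).
#' @return a [label_components()] `LabelVolume`.
#' @export
binarize_and_label <- function(volume, sensitivity = 0.5, window = 31L,
                               min_size = 27L) {
  if (is.matrix(volume)) volume <- array(volume, c(1L, dim(volume)))
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (sensitivity < 0 || sensitivity > 1) stop("sensitivity must be in [0, 1]")
  mu <- box_mean_3d(volume, window)
  mask <- volume > mu * (1 + (1 - sensitivity))
  label_components(mask, min_size = min_size)
}

#' Directional volume-overlap colocalization index
#'
#' The overlap volume `O` between the two foregrounds as a percentage of
#' each: `pct_in_a = 100 * O / |A|`, `pct_in_b = 100 * O / |B|`. Exact
#' integer voxel arithmetic. An empty channel yields 0 for its direction
#' with attribute `empty`.
#'
#' @param a,b `LabelVolume`s (or logical arrays) of the same shape.
#' @return named numeric `c(pct_in_a, pct_in_b)`.
#' @export
coloc_index <- function(a, b) {
  fa <- if (inherits(a, "LabelVolume")) a$labels > 0L else as.logical(a)
  fb <- if (inherits(b, "LabelVolume")) b$labels > 0L else as.logical(b)
  if (length(fa) != length(fb)) stop("volumes differ in shape")
  na <- sum(fa); nb <- sum(fb)
  o <- sum(fa & fb)
  out <- c(pct_in_a = if (na > 0) 100 * o / na else 0,
           pct_in_b = if (nb > 0) 100 * o / nb else 0)
  if (na == 0 || nb == 0) attr(out, "empty") <- c(a = na == 0, b = nb == 0)
  out
}

#' Pairwise colocalization matrix of a multichannel volume
#'
#' Each channel is segmented by [binarize_and_label()] with its own
#' parameters; entry `(i, j)` is the percentage of channel i's particle
#' volume overlapped by channel j's (row = reference channel, the
#' convention recorded in the result). The diagonal is 100 for non-empty
#' channels; empty channels produce zero rows/columns and are flagged.
#'
#' @param stack an [image_stack()] (or plain `(c, z, y, x)` array) with >= 2
#'   channels; channels must already be registered.
#' @param per_channel_params optional list (length C) of per-channel
#'   overrides: `sensitivity`, `window`, `min_size`.
#' @param sensitivity,window,min_size defaults applied to every channel.
#' @param roi_id identifier carried into the result.
#' @return object of class `ColocMatrix`: `values` (C x C percentages),
#'   `channel_names`, `roi_id`, attributes `convention` and `empty_channels`.
#' @export
coloc_matrix <- function(stack, per_channel_params = NULL, sensitivity = 0.5,
                         window = 31L, min_size = 27L, roi_id = "roi1") {
  if (inherits(stack, "ImageStack")) {
    dat <- stack$data; chn <- stack$channel_names
  } else {
    dat <- stack; chn <- paste0("ch", seq_len(dim(stack)[1]))
  }
  C <- dim(dat)[1]
  if (C < 2) stop("need at least 2 channels")
  fg <- vector("list", C)
  for (i in seq_len(C)) {
    p <- if (!is.null(per_channel_params)) per_channel_params[[i]] else NULL
    lv <- binarize_and_label(array(dat[i, , , ], dim(dat)[2:4]),
                             sensitivity = p$sensitivity %||% sensitivity,
                             window = p$window %||% window,
                             min_size = p$min_size %||% min_size)
    fg[[i]] <- lv$labels > 0L
  }
  vol <- vapply(fg, sum, numeric(1))
  M <- matrix(0, C, C, dimnames = list(chn, chn))
  for (i in seq_len(C)) for (j in seq_len(C)) {
    if (vol[i] > 0) M[i, j] <- 100 * sum(fg[[i]] & fg[[j]]) / vol[i]
  }
  structure(list(values = M, channel_names = chn, roi_id = roi_id),
            class = "ColocMatrix",
            convention = "row = reference channel: values[i, j] = % of channel i volume overlapped by channel j",
            empty_channels = chn[vol == 0])
}

#' @export
print.ColocMatrix <- function(x, ...) {
  cat(sprintf("ColocMatrix (%s): %d channels, row-referenced %%\n",
              x$roi_id, length(x$channel_names)))
  print(round(x$values, 1))
  invisible(x)
}

#' Delta-colocalization matrix with per-cell one-way ANOVA
#'
#' Compares two ROI groups (e.g. wildtype vs mutant cells): per matrix cell,
#' the group means, their difference `delta = mean(group2) - mean(group1)`,
#' and the one-way ANOVA p-value across ROI-level values (two groups, so the
#' F test has 1 and n-2 df). Stars follow the 0.05 / 0.01 / 0.001
#' convention. Degenerate cells (no variance) get p = 1 and are flagged.
#' No multiple-testing correction by default; `p_adjust = "BH"` applies
#' Benjamini-Hochberg across all cells.
#'
#' @param group1,group2 lists of [coloc_matrix()] results (>= 2 ROIs each)
#'   with matching channels.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return object of class `DeltaResult`: `delta`, `mean1`, `mean2`,
#'   `p_values`, `stars` (C x C character), `degenerate` (logical C x C),
#'   `n1`, `n2`.
#' @export
delta_matrix_anova <- function(group1, group2, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (length(group1) < 2 || length(group2) < 2)
    stop("need at least 2 ROIs per group")
  chn <- group1[[1]]$channel_names
  all_m <- c(group1, group2)
  for (m in all_m)
    if (!identical(m$channel_names, chn)) stop("channel names differ across ROIs")
  C <- length(chn)
  g <- factor(rep(c("g1", "g2"), c(length(group1), length(group2))))
  a1 <- simplify2array(lapply(group1, `[[`, "values"))   # C x C x n1
  a2 <- simplify2array(lapply(group2, `[[`, "values"))
  mean1 <- apply(a1, c(1, 2), mean); mean2 <- apply(a2, c(1, 2), mean)
  pmat <- matrix(1, C, C, dimnames = list(chn, chn))
  degen <- matrix(FALSE, C, C, dimnames = list(chn, chn))
  for (i in seq_len(C)) for (j in seq_len(C)) {
    v <- c(a1[i, j, ], a2[i, j, ])
    if (stats::var(v) < 1e-12) { degen[i, j] <- TRUE; next }
    fit <- stats::anova(stats::lm(v ~ g))
    pmat[i, j] <- fit[["Pr(>F)"]][1]
  }
  if (p_adjust == "BH") {
    adj <- stats::p.adjust(pmat[!degen], method = "BH")
    pmat[!degen] <- adj
  }
  stars <- matrix("", C, C, dimnames = list(chn, chn))
  stars[pmat < 0.05] <- "*"
  stars[pmat < 0.01] <- "**"
  stars[pmat < 0.001] <- "***"
  stars[degen] <- ""
  structure(list(delta = mean2 - mean1, mean1 = mean1, mean2 = mean2,
                 p_values = pmat, stars = stars, degenerate = degen,
                 n1 = length(group1), n2 = length(group2)),
            class = "DeltaResult")
}

#' @export
print.DeltaResult <- function(x, ...) {
  cat(sprintf("DeltaResult: mean(group2) - mean(group1), n = %d / %d ROIs\n",
              x$n1, x$n2))
  d <- round(x$delta, 1)
  out <- matrix(paste0(d, x$stars), nrow(d), dimnames = dimnames(d))
  print(out, quote = FALSE)
  invisible(x)
}
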