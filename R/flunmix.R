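#' Mutual information between two images
#'
#' Shannon mutual information (nats) from the joint histogram of min-max
#' normalized intensities with `n_bins` per axis:
#' `I = sum p(a,b) * log(p(a,b) / (p(a) p(b)))`. Independence gives 0; a
#' deterministic relation gives the marginal entropy. A constant image on
#' either side returns 0 with attribute `degenerate = TRUE`.
#'
#' @param img_a,img_b same-shape numeric arrays.
#' @param n_bins histogram bins per axis (>= 2).
#' @return MI in nats (>= 0 up to round-off), possibly with attribute
#'   `degenerate`.
#' @export
mutual_information <- function(img_a, img_b, n_bins = 64L) {
  if (length(img_a) != length(img_b)) stop("images must have the same shape")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  ia <- .mi_bin(img_a, n_bins)
  ib <- .mi_bin(img_b, n_bins)
  if (is.null(ia) || is.null(ib))
    return(structure(0, degenerate = TRUE))
  .mi_from_bins(ia, ib, n_bins)
}

# bin a vector to 1..n_bins after min-max normalization; NULL when constant
.mi_bin <- function(x, n_bins) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(NULL)
  pmin(floor((as.vector(x) - lo) / (hi - lo) * n_bins), n_bins - 1L) + 1L
}

.mi_from_bins <- function(ia, ib, n_bins) {
  joint <- tabulate((ia - 1L) * n_bins + ib, n_bins * n_bins)
  n <- length(ia)
  pj <- joint[joint > 0] / n
  pa <- tabulate(ia, n_bins) / n
  pb <- tabulate(ib, n_bins) / n
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  hj <- -sum(pj * log(pj))
  max(ha + hb - hj, 0)
}

#' Find the carry-over coefficient minimizing mutual information
#'
#' Cumulative staining makes round `i` observe its own true signal plus a
#' carry-over `alpha` times the previous accumulated round. Since the two
#' rounds target distinct molecules, the true signal should share no
#' information with the previous image: the optimal `alpha` is the grid
#' value minimizing `MI(prev, curr - alpha * prev)`. The residual is *not*
#' clipped inside the search: clipping would let arbitrary oversubtraction
#' drive the residual entropy (and with it the MI) to zero, so the minimum
#' would degenerate to the top of the grid; unclipped, oversubtraction
#' re-introduces (negative) dependence on `prev` and the MI has an interior
#' minimum at the true carry-over. Non-negativity is enforced on the output
#' image only. Ties resolve to the smallest `alpha`; an all-zero `prev`
#' returns `alpha = 0` with a degenerate flag.
#'
#' Both images are background-subtracted (1st percentile) before the search
#' so shared background does not dominate the MI.
#'
#' @param prev,curr registered same-shape images (previous accumulated round
#'   and current round, one channel).
#' @param alpha_grid sorted candidate coefficients (default `seq(0, 1.5,
#'   by = 0.01)`).
#' @param n_bins MI histogram bins.
#' @return list `alpha_opt`, `mi_profile` (data.frame `alpha`, `mi`),
#'   `degenerate`.
#' @export
find_alpha_opt <- function(prev, curr, alpha_grid = seq(0, 1.5, by = 0.01),
                           n_bins = 64L) {
  if (length(prev) != length(curr)) stop("images must have the same shape")
  if (length(alpha_grid) == 0) stop("alpha_grid is empty")
  alpha_grid <- sort(alpha_grid)
  p <- as.vector(prev) - stats::quantile(prev, 0.01, names = FALSE)
  c_ <- as.vector(curr) - stats::quantile(curr, 0.01, names = FALSE)
  p <- pmax(p, 0); c_ <- pmax(c_, 0)
  ip <- .mi_bin(p, n_bins)
  if (is.null(ip) || max(p) == 0) {
    return(list(alpha_opt = 0,
                mi_profile = data.frame(alpha = alpha_grid,
                                        mi = rep(0, length(alpha_grid))),
                degenerate = TRUE))
  }
  mi <- vapply(alpha_grid, function(a) {
    r <- c_ - a * p
    ir <- .mi_bin(r, n_bins)
    if (is.null(ir)) 0 else .mi_from_bins(ip, ir, n_bins)
  }, numeric(1))
  k <- which.min(mi)   # which.min takes the first (smallest alpha) on ties
  list(alpha_opt = alpha_grid[k],
       mi_profile = data.frame(alpha = alpha_grid, mi = mi),
       degenerate = FALSE)
}

#' Unmix a registered cumulative-staining round series
#'
#' Recovers the true per-round signal from accumulated observations: for
#' every non-reference channel and every round `i >= 2`, the carry-over
#' coefficient is estimated by [find_alpha_opt()] against the previous
#' observed round of the same channel, and the true image is
#' `clip(Image_i - alpha_opt * Image_{i-1}, 0)`. Round 1 passes through
#' unchanged; the reference channel is never unmixed. Channels are treated
#' independently.
#'
#' @param series a registered `RoundSeries`.
#' @param alpha_grid,n_bins passed to [find_alpha_opt()].
#' @return object of class `UnmixResult`: `alpha_opt` (matrix channel x
#'   transition), `true_images` (`[[round]][[channel name]]` arrays,
#'   reference channel included untouched), `mi_profiles` (nested list),
#'   `channel_names`, `reference_channel`.
#' @export
unmix_series <- function(series, alpha_grid = seq(0, 1.5, by = 0.01),
                         n_bins = 64L) {
  stopifnot(inherits(series, "RoundSeries"))
  n_rounds <- length(series$rounds)
  if (n_rounds < 2) stop("need at least 2 rounds")
  chn <- series$rounds[[1]]$channel_names
  d1 <- dim(series$rounds[[1]]$data)
  for (i in seq_len(n_rounds))
    if (!all(dim(series$rounds[[i]]$data) == d1))
      stop("round ", i, " shape differs from round 1")
  unmix_ch <- setdiff(chn, series$reference_channel)
  alpha <- matrix(NA_real_, length(unmix_ch), n_rounds - 1L,
                  dimnames = list(unmix_ch, paste0("r", 2:n_rounds)))
  profiles <- lapply(unmix_ch, function(.) vector("list", n_rounds - 1L))
  names(profiles) <- unmix_ch
  true_images <- vector("list", n_rounds)
  for (i in seq_len(n_rounds)) {
    true_images[[i]] <- lapply(seq_along(chn), function(ci)
      series$rounds[[i]]$data[ci, , , , drop = TRUE])
    names(true_images[[i]]) <- chn
  }
  for (ch in unmix_ch) {
    ci <- match(ch, chn)
    for (i in 2:n_rounds) {
      prev <- series$rounds[[i - 1]]$data[ci, , , ]
      curr <- series$rounds[[i]]$data[ci, , , ]
      fit <- find_alpha_opt(prev, curr, alpha_grid = alpha_grid, n_bins = n_bins)
      alpha[ch, i - 1L] <- fit$alpha_opt
      profiles[[ch]][[i - 1L]] <- fit$mi_profile
      out <- pmax(curr - fit$alpha_opt * prev, 0)
      dim(out) <- dim(true_images[[i]][[ch]])
      true_images[[i]][[ch]] <- out
    }
  }
  structure(list(alpha_opt = alpha, true_images = true_images,
                 mi_profiles = profiles, channel_names = chn,
                 reference_channel = series$reference_channel),
            class = "UnmixResult")
}

#' @export
print.UnmixResult <- function(x, ...) {
  cat(sprintf("UnmixResult: %d rounds, reference '%s'\nalpha_opt:\n",
              length(x$true_images), x$reference_channel))
  print(round(x$alpha_opt, 3))
  invisible(x)
}
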