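# Independent oracles used to cross-check package results. These deliberately
# share no code with the implementation: plain-R flood fill, histogram
# entropies, brute-force voxel counting.

# 26-connectivity labeling by explicit flood fill over a (z, y, x) logical
# array, visiting all 26 neighbour offsets.
oracle_flood_label <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (lab[p[1], p[2], p[3]] != 0L) next
    nxt <- nxt + 1L
    stack <- list(p)
    lab[p[1], p[2], p[3]] <- nxt
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        w <- v + offs[k, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- nxt
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
  }
  lab
}

# Shannon entropy (nats) of a histogram of x with n_bins over its min-max range
oracle_entropy <- function(x, n_bins = 64L) {
  lo <- min(x); hi <- max(x)
  b <- pmin(floor((as.vector(x) - lo) / (hi - lo) * n_bins), n_bins - 1L)
  p <- table(b) / length(x)
  -sum(p * log(p))
}

# Mutual information from explicit joint table construction
oracle_mi <- function(a, b, n_bins = 64L) {
  bin <- function(x) {
    lo <- min(x); hi <- max(x)
    pmin(floor((as.vector(x) - lo) / (hi - lo) * n_bins), n_bins - 1L)
  }
  ia <- bin(a); ib <- bin(b)
  jt <- table(factor(ia, levels = 0:(n_bins - 1)),
              factor(ib, levels = 0:(n_bins - 1))) / length(ia)
  pa <- rowSums(jt); pb <- colSums(jt)
  s <- 0
  for (i in seq_len(n_bins)) for (j in seq_len(n_bins)) {
    if (jt[i, j] > 0) s <- s + jt[i, j] * log(jt[i, j] / (pa[i] * pb[j]))
  }
  as.numeric(s)
}

# Brute-force overlap percentages by an explicit voxel loop
oracle_coloc <- function(fa, fb) {
  o <- 0L; na <- 0L; nb <- 0L
  for (i in seq_along(fa)) {
    if (fa[i]) na <- na + 1L
    if (fb[i]) nb <- nb + 1L
    if (fa[i] && fb[i]) o <- o + 1L
  }
  c(if (na > 0) 100 * o / na else 0, if (nb > 0) 100 * o / nb else 0)
}

# Closed-form two-group one-way ANOVA p-value (F test, 1 and n-2 df)
oracle_anova_p <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2); n <- n1 + n2
  gm <- mean(c(x1, x2))
  ssb <- n1 * (mean(x1) - gm)^2 + n2 * (mean(x2) - gm)^2
  ssw <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
  f <- ssb / (ssw / (n - 2))
  stats::pf(f, 1, n - 2, lower.tail = FALSE)
}

# Small blob image for registration fixtures
helper_blob_image <- function(ny = 96, nx = 96, n = 40, seed = 1) {
  set.seed(seed)
  exmquant:::render_blobs(ny, nx,
                          cbind(runif(n, 8, ny - 8), runif(n, 8, nx - 8)),
                          cbind(runif(n, 2, 3.5), runif(n, 2, 3.5)),
                          runif(n, 0, pi), runif(n, 0.4, 1))
}
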