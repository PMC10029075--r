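test_that("self-matching an image yields zero-displacement matches", {
  img <- helper_blob_image(96, 96, n = 35, seed = 4)
  m <- detect_and_match_keypoints(img, img, sigma_range_b = c(1.5, 8))
  d <- sqrt(rowSums((m$points_a - m$points_b)^2))
  expect_gte(mean(d < 1e-9), 0.9)
})

test_that("matching a scaled copy lands truth blobs within 2 px", {
  g <- gen_expansion_pair(n_objects = 35, scale = 4, rotation = 0.1,
                          translation = c(4, -2), seed = 5, n_z = 3,
                          min_separation = 10)
  proj <- max_project(g$post)
  m <- detect_and_match_keypoints(g$pre, proj)
  fit <- fit_similarity_ransac(m, inlier_tol = 3, seed = 2)
  pa <- fit$matches$points_a[fit$matches$inlier_mask, , drop = FALSE]
  pb <- fit$matches$points_b[fit$matches$inlier_mask, , drop = FALSE]
  pred <- apply_transform(g$truth$transform, pa)
  expect_gte(nrow(pa), 4)
  expect_lt(max(sqrt(rowSums((pred - pb)^2))), 2)
})

test_that("degenerate images raise an insufficient-keypoints error", {
  img <- helper_blob_image(64, 64, n = 20, seed = 6)
  expect_error(detect_and_match_keypoints(matrix(3, 64, 64), img), "constant")
  expect_error(detect_keypoints(matrix(0, 32, 32)), "constant")
})

test_that("similarity RANSAC recovers clean transforms to machine precision", {
  set.seed(7)
  pa <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  tr0 <- similarity_transform(3.7, 0.4, c(12, -5))
  pb <- apply_transform(tr0, pa)
  fit <- fit_similarity_ransac(match_set(pa, pb), inlier_tol = 1, seed = 3)
  expect_lt(abs(fit$transform$scale - 3.7), 1e-6)
  expect_lt(abs(fit$transform$rotation - 0.4), 1e-6)
  expect_lt(max(abs(fit$transform$translation - c(12, -5))), 1e-6)
  # identity correspondences
  fid <- fit_similarity_ransac(match_set(pa, pa), inlier_tol = 1, seed = 3)
  expect_equal(fid$transform$scale, 1, tolerance = 1e-9)
  expect_equal(fid$transform$rotation, 0, tolerance = 1e-9)
  expect_equal(fid$transform$translation, c(0, 0), tolerance = 1e-9)
})

test_that("similarity fit agrees with an independent Procrustes oracle", {
  skip_if_not_installed("vegan")
  set.seed(8)
  pa <- cbind(runif(30, 0, 50), runif(30, 0, 50))
  pb <- apply_transform(similarity_transform(2.1, -0.3, c(3, 9)), pa) +
    matrix(rnorm(60, 0, 0.05), 30, 2)
  fit <- fit_similarity_ransac(match_set(pa, pb), inlier_tol = 2, seed = 1)
  pr <- vegan::procrustes(pb, pa)   # Y rotated/scaled onto X
  expect_equal(fit$transform$scale, pr$scale, tolerance = 1e-6)
  ang <- atan2(pr$rotation[2, 1], pr$rotation[1, 1])
  expect_equal(abs(fit$transform$rotation), abs(ang), tolerance = 1e-6)
})

test_that("RANSAC tolerates 30% gross outliers with 0.1% scale accuracy", {
  set.seed(9)
  pa <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  tr0 <- similarity_transform(3.7, 0.4, c(12, -5))
  pb <- apply_transform(tr0, pa)
  pa2 <- rbind(pa, cbind(runif(21, 0, 100), runif(21, 0, 100)))
  pb2 <- rbind(pb, cbind(runif(21, 0, 400), runif(21, 0, 400)))
  fit <- fit_similarity_ransac(match_set(pa2, pb2), inlier_tol = 2, seed = 3)
  expect_lt(abs(fit$transform$scale - 3.7) / 3.7, 0.001)
})

test_that("RANSAC is seed-reproducible and inliers grow with tolerance", {
  set.seed(10)
  pa <- cbind(runif(40, 0, 80), runif(40, 0, 80))
  pb <- apply_transform(similarity_transform(1.5, 0.1, c(2, 2)), pa) +
    matrix(rnorm(80, 0, 0.8), 40, 2)
  f1 <- fit_similarity_ransac(match_set(pa, pb), inlier_tol = 1.5, seed = 5)
  f2 <- fit_similarity_ransac(match_set(pa, pb), inlier_tol = 1.5, seed = 5)
  expect_identical(f1$transform, f2$transform)
  expect_identical(f1$matches$inlier_mask, f2$matches$inlier_mask)
  tols <- c(0.5, 1, 2, 4)
  ni <- vapply(tols, function(tl)
    suppressWarnings(fit_similarity_ransac(match_set(pa, pb), inlier_tol = tl,
                                           seed = 5))$n_inliers,
    numeric(1))
  expect_true(all(diff(ni) >= 0))
})

test_that("recovered scale is equivariant under a common rotation", {
  set.seed(11)
  pa <- cbind(runif(25, -40, 40), runif(25, -40, 40))
  pb <- apply_transform(similarity_transform(2.5, 0.2, c(1, -1)), pa)
  rot <- similarity_transform(1, 0.7, c(0, 0))
  f0 <- fit_similarity_ransac(match_set(pa, pb), seed = 2)
  f1 <- fit_similarity_ransac(match_set(apply_transform(rot, pa),
                                        apply_transform(rot, pb)), seed = 2)
  expect_equal(f1$transform$scale, f0$transform$scale, tolerance = 1e-9)
})

test_that("transform inversion composes to the identity", {
  tr <- similarity_transform(4.97, 0.33, c(10.5, -7.2))
  p <- cbind(c(0, 13.7, -4), c(5, 2.2, 9))
  back <- apply_transform(invert_transform(tr), apply_transform(tr, p))
  expect_lt(max(abs(back - p)), 1e-9)
})

test_that("the best z window overlaps the planes holding the scene", {
  g <- gen_expansion_pair(n_objects = 40, scale = 2, rotation = 0.03,
                          translation = c(2, 1), seed = 6, n_z = 15)
  bz <- find_best_z_projection(g$pre, g$post, window_lengths = c(5, 8), stride = 2,
                               sigma_range_b = c(1.5, 12))
  zc <- g$truth$z_content
  expect_lt(bz$z_window[1], zc[2] + 1)   # window starts before content ends
  expect_gt(bz$z_window[2], zc[1])       # and ends after it begins
  expect_gte(bz$n_inliers, 4)
})

test_that("single-plane stacks reduce the z search to direct matching", {
  g <- gen_expansion_pair(n_objects = 35, scale = 2, seed = 7, n_z = 1)
  bz <- find_best_z_projection(g$pre, g$post, window_lengths = 1,
                               sigma_range_b = c(1.5, 10))
  expect_equal(bz$z_window, c(0, 1))
  expect_equal(bz$projection, g$post$data[1, 1, , ])
})

test_that("demons returns a null field for identical images", {
  img <- helper_blob_image(64, 64, n = 25, seed = 12)
  f <- demons_refine(img, img, n_iter = 10)
  expect_lt(max(abs(c(f$dy, f$dx))), 1e-3)
})

test_that("demons recovers a known smooth warp within 1 px", {
  img <- helper_blob_image(128, 128, n = 60, seed = 13)
  wf <- exmquant:::with_seed(9, exmquant:::smooth_random_field(128, 128, 3))
  moving <- warp_image(img, displacement_field(wf$dy, wf$dx))
  f <- demons_refine(moving, img, n_iter = 100, smoothing_sigma = 2)
  epe <- sqrt((f$dy + wf$dy)^2 + (f$dx + wf$dx)^2)
  expect_lt(mean(epe), 1)
  r <- attr(f, "residuals")
  expect_lt(r[length(r)], r[1])
  # non-increasing up to numerical jitter at convergence
  expect_true(all(diff(r) <= 1e-6 * r[1]))
})

test_that("multi-round registration undoes rigid offsets on the reference", {
  g <- gen_round_series(n_rounds = 2, n_channels = 2, alpha_per_round = 0.3,
                        offsets = rbind(c(0, 0), c(4, -3)),
                        shape = c(1, 96, 96), seed = 14)
  reg <- suppressWarnings(register_rounds(g$series, demons = TRUE, demons_iter = 15))
  tr <- attr(reg, "transforms")[[2]]
  expect_equal(tr$scale, 1)
  expect_lt(max(abs(tr$translation - c(-4, 3))), 0.2)
  # alignment improves the reference-channel correlation between rounds
  r1 <- g$series$rounds[[1]]$data[1, 1, , ]
  before <- stats::cor(as.vector(r1), as.vector(g$series$rounds[[2]]$data[1, 1, , ]))
  after <- stats::cor(as.vector(r1), as.vector(reg$rounds[[2]]$data[1, 1, , ]))
  expect_gt(after, before)
  expect_gt(after, 0.98)
})
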