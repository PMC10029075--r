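test_that("generators are deterministic given a seed", {
  g1 <- gen_expansion_pair(scale = 3, seed = 42, pre_size = c(64, 64), n_z = 4)
  g2 <- gen_expansion_pair(scale = 3, seed = 42, pre_size = c(64, 64), n_z = 4)
  g3 <- gen_expansion_pair(scale = 3, seed = 43, pre_size = c(64, 64), n_z = 4)
  expect_identical(g1$pre, g2$pre)
  expect_identical(g1$post$data, g2$post$data)
  expect_identical(g1$truth$keypoint_truth, g2$truth$keypoint_truth)
  expect_false(identical(g1$pre, g3$pre))

  r1 <- gen_round_series(seed = 7, shape = c(1, 48, 48))
  r2 <- gen_round_series(seed = 7, shape = c(1, 48, 48))
  expect_identical(r1$series$rounds[[2]]$data, r2$series$rounds[[2]]$data)

  m1 <- gen_blinking_movie(emitter_truth(cbind(16, 16)), 50, seed = 5, shape = c(32, 32))
  m2 <- gen_blinking_movie(emitter_truth(cbind(16, 16)), 50, seed = 5, shape = c(32, 32))
  expect_identical(m1$frames, m2$frames)
})

test_that("identity-parameter expansion pair reproduces the pre image", {
  g <- gen_expansion_pair(scale = 1, rotation = 0, translation = c(0, 0),
                          warp_amplitude = 0, noise_sd = 0, photons = Inf,
                          n_z = 1, seed = 3, pre_size = c(64, 64))
  kt <- g$truth$keypoint_truth
  # blob centres map by the pure padding translation
  expect_equal(kt$post_y, kt$pre_y + 14, tolerance = 1e-12)
  expect_equal(kt$post_x, kt$pre_x + 14, tolerance = 1e-12)
  centre <- g$post$data[1, 1, 15:78, 15:78]
  # identical up to blob tails clipped at the smaller pre frame
  expect_lt(max(abs(centre - g$pre)), 0.02)
})

test_that("stored transform maps truth keypoints exactly when warp is zero", {
  g <- gen_expansion_pair(scale = 4, rotation = 0.2, translation = c(5, -3),
                          warp_amplitude = 0, seed = 8, pre_size = c(64, 64), n_z = 3)
  kt <- g$truth$keypoint_truth
  pred <- apply_transform(g$truth$transform, as.matrix(kt[, c("pre_y", "pre_x")]))
  expect_equal(pred[, 1], kt$post_y, tolerance = 1e-9)
  expect_equal(pred[, 2], kt$post_x, tolerance = 1e-9)
  expect_error(gen_expansion_pair(scale = 0), "scale")
  expect_error(gen_expansion_pair(warp_amplitude = -1), "warp")
})

test_that("warp amplitude bounds the similarity-fit residual on truth points", {
  g <- gen_expansion_pair(scale = 2, rotation = 0.05, warp_amplitude = 2,
                          seed = 9, pre_size = c(96, 96), n_z = 3)
  kt <- g$truth$keypoint_truth
  fit <- exmquant:::fit_similarity_ls(as.matrix(kt[, 1:2]), as.matrix(kt[, 3:4]))
  res <- apply_transform(fit, as.matrix(kt[, 1:2])) - as.matrix(kt[, 3:4])
  mags <- sqrt(rowSums(res^2))
  expect_gt(mean(mags), 0)
  # residual after removing the best similarity cannot exceed the injected
  # displacement bound (the fit removes part of it)
  expect_lte(max(mags), 2 + 1e-6)
})

test_that("round series obeys the recursive carry-over arithmetic", {
  # alpha = 0, no offsets, no noise, no baseline: observed equals truth
  g0 <- gen_round_series(n_rounds = 3, n_channels = 3, alpha_per_round = c(0, 0),
                         noise_sd = 0, background = 0, shape = c(1, 48, 48), seed = 2)
  for (i in 1:3) for (c in 2:3) {
    expect_equal(array(g0$series$rounds[[i]]$data[c, , , ], c(1, 48, 48)),
                 g0$truth$true_images[[i]][[c]], tolerance = 1e-12)
  }
  # alpha = 0.4: Image_2 - 0.4 * Image_1 recovers ImageR_2 voxelwise
  g <- gen_round_series(n_rounds = 2, n_channels = 2, alpha_per_round = 0.4,
                        noise_sd = 0, background = 0, shape = c(1, 48, 48), seed = 2)
  diffed <- g$series$rounds[[2]]$data[2, 1, , ] - 0.4 * g$series$rounds[[1]]$data[2, 1, , ]
  expect_equal(array(diffed, c(1, 48, 48)), g$truth$true_images[[2]][[2]],
               tolerance = 1e-12)
  expect_error(gen_round_series(alpha_per_round = c(-0.1, 0)), "alpha")
  expect_error(gen_round_series(n_rounds = 1), "n_rounds")
})

test_that("default round series matches the three-cycle ten-color panel", {
  g <- gen_round_series(seed = 1, shape = c(1, 48, 48))
  expect_length(g$series$rounds, 3)            # three staining cycles
  expect_equal(g$series$reference_channel, "DAPI")
  expect_length(g$truth$marker_names, 9)       # 9 markers + DAPI = 10 colors
})

test_that("label volumes have exact voxel counts and overlaps", {
  g <- gen_label_volumes(c(24, 24, 24), c(1000, 500), 0.5, seed = 3)
  expect_equal(sum(g$mask_a), 1000)
  expect_equal(sum(g$mask_b), 500)
  expect_equal(sum(g$mask_a & g$mask_b), 250)
  expect_equal(g$truth$frac_in_a, 0.25)
  expect_equal(g$truth$frac_in_b, 0.5)
  # full overlap of equal volumes -> identical masks
  ge <- gen_label_volumes(c(16, 16, 16), c(300, 300), 1, seed = 4)
  expect_identical(ge$mask_a, ge$mask_b)
  # zero overlap -> disjoint
  gd <- gen_label_volumes(c(16, 16, 16), c(300, 300), 0, seed = 5)
  expect_equal(sum(gd$mask_a & gd$mask_b), 0)
  expect_error(gen_label_volumes(c(4, 4, 4), c(300, 300), 0, seed = 1),
               "infeasible")
  # each generated region is one connected component
  expect_equal(label_components(g$mask_a)$n_particles, 1)
  expect_equal(label_components(g$mask_b)$n_particles, 1)
})

test_that("coloc volume chains reproduce requested neighbour overlaps", {
  cv <- gen_coloc_volumes(c(20, 48, 48), rep(600, 4), c(0.5, 0.25, 0.4), seed = 6)
  tm <- cv$truth_matrix
  expect_equal(diag(tm), rep(100, 4))
  expect_equal(tm[1, 2], 50)
  expect_equal(tm[2, 3], 25)
  expect_equal(tm[3, 4], 40)
  expect_equal(tm[1, 3], 0)
})

test_that("blinking movies have two-state statistics and Gaussian spots", {
  # always-on emitter: every pixel's temporal variance is shot noise only
  et <- emitter_truth(cbind(16, 16), p_on = 1, p_off = 0, photon_rate = 500)
  mv <- gen_blinking_movie(et, n_frames = 300, background = 5, shape = c(32, 32), seed = 2)
  mu <- apply(mv$frames, c(2, 3), mean)
  vv <- apply(mv$frames, c(2, 3), stats::var)
  # Poisson: var == mean; compare the image-wide averages
  expect_equal(mean(vv), mean(mu), tolerance = 0.05)
  expect_true(all(attr(mv, "states")))
  # single bright emitter: the mean image is a Gaussian of width psf_sigma
  et2 <- emitter_truth(cbind(16.0, 16.0), p_on = 1, p_off = 0,
                       psf_sigma = 2.5, photon_rate = 2e5)
  mv2 <- gen_blinking_movie(et2, n_frames = 50, background = 0, shape = c(32, 32), seed = 3)
  expect_equal(exmquant:::spot_sigma(apply(mv2$frames, c(2, 3), mean)), 2.5,
               tolerance = 0.05)
  expect_error(emitter_truth(cbind(1, 1), p_on = 1.2), "probabilities")
  expect_error(emitter_truth(cbind(1, 1), psf_sigma = 0), "psf_sigma")
})
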