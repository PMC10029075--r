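test_that("adaptive thresholding and labeling segment constructed volumes", {
  # bright 4x4x4 cube on a dark background: one 64-voxel particle
  vol <- array(0.05, c(12, 12, 12))
  vol[3:6, 3:6, 3:6] <- 1
  lv <- binarize_and_label(vol, sensitivity = 0.5, window = 11, min_size = 27)
  expect_equal(lv$n_particles, 1)
  expect_equal(lv$particle_sizes, 64L)
  # a 26-voxel speck falls below the default min_size of 27
  vol2 <- array(0.05, c(16, 16, 16))
  vol2[2:4, 2:4, 2:4] <- 1          # 27 voxels
  vol2[2, 2, 2] <- 0.05             # carve one out -> 26-voxel component
  lv2 <- binarize_and_label(vol2, window = 11, min_size = 27)
  expect_equal(lv2$n_particles, 0)
  lv3 <- binarize_and_label(vol2, window = 11, min_size = 26)
  expect_equal(lv3$n_particles, 1)
  expect_equal(lv3$particle_sizes, 26L)
  expect_error(binarize_and_label(vol, window = 10), "odd")
  expect_error(binarize_and_label(vol, sensitivity = 2), "sensitivity")
  # all-background input is a valid empty volume
  empty <- binarize_and_label(array(1, c(8, 8, 8)), window = 5)
  expect_equal(empty$n_particles, 0)
})

test_that("two cubes touching at a corner are one 26-connected particle", {
  v <- array(FALSE, c(8, 8, 8))
  v[2:3, 2:3, 2:3] <- TRUE
  v[4:5, 4:5, 4:5] <- TRUE
  lv <- label_components(v)
  expect_equal(lv$n_particles, 1)
  o <- oracle_flood_label(v)
  expect_equal(max(o), 1)
})

test_that("26-connectivity labeling agrees with a flood-fill oracle", {
  set.seed(31)
  for (rep in 1:25) {
    m <- array(runif(16^3) < 0.18, c(16, 16, 16))
    lv <- label_components(m)
    o <- oracle_flood_label(m)
    expect_equal(lv$n_particles, max(o))
    # same partition: label maps must be a bijection on components
    if (max(o) > 0) {
      tab <- table(lv$labels[m], o[m])
      expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    }
    expect_equal(sort(lv$particle_sizes),
                 sort(as.integer(table(o[o > 0]))))
  }
})

test_that("coloc_index is exact integer voxel arithmetic", {
  g <- gen_label_volumes(c(24, 24, 24), c(1000, 500), 0.5, seed = 7)
  expect_equal(unname(coloc_index(g$mask_a, g$mask_b)), c(25.0, 50.0))
  # identical and disjoint masks
  expect_equal(unname(coloc_index(g$mask_a, g$mask_a)), c(100, 100))
  gd <- gen_label_volumes(c(16, 16, 16), c(200, 200), 0, seed = 8)
  expect_equal(unname(coloc_index(gd$mask_a, gd$mask_b)), c(0, 0))
  # empty channel flags
  e <- coloc_index(array(FALSE, c(4, 4, 4)), gd$mask_a[1:4, 1:4, 1:4])
  expect_equal(as.numeric(e), c(0, 0))
  expect_true(attr(e, "empty")["a"])
  # brute-force double-loop agreement on random masks
  set.seed(32)
  for (rep in 1:20) {
    a <- array(runif(16^3) < 0.2, c(16, 16, 16))
    b <- array(runif(16^3) < 0.2, c(16, 16, 16))
    expect_identical(unname(coloc_index(a, b)), oracle_coloc(a, b))
  }
  expect_error(coloc_index(g$mask_a, gd$mask_a), "shape")
})

test_that("coloc matrices follow the row-reference convention", {
  cv <- gen_coloc_volumes(c(20, 64, 64), rep(700, 3), c(0.4, 0.2), seed = 9)
  dat <- array(0, c(3, 20, 64, 64))
  for (k in 1:3) dat[k, , , ] <- as.numeric(cv$masks[[k]]) + 0.1
  st <- image_stack(dat, pixel_size_xy = 1, pixel_size_z = 1,
                    channel_names = c("A", "B", "C"))
  cm <- coloc_matrix(st)
  expect_equal(unname(cm$values), unname(cv$truth_matrix), tolerance = 1e-9)
  expect_equal(diag(cm$values), c(A = 100, B = 100, C = 100))
  # permuting channel order permutes the matrix consistently (P M P^T)
  perm <- c(3, 1, 2)
  st_p <- image_stack(dat[perm, , , , drop = FALSE], pixel_size_xy = 1,
                      pixel_size_z = 1, channel_names = c("C", "A", "B"))
  cm_p <- coloc_matrix(st_p)
  expect_equal(unname(cm_p$values), unname(cm$values[perm, perm]), tolerance = 1e-9)
  # all channels identical -> all 100
  same <- image_stack(dat[c(1, 1), , , , drop = FALSE], pixel_size_xy = 1,
                      pixel_size_z = 1, channel_names = c("x", "y"))
  expect_true(all(coloc_matrix(same)$values == 100))
})

test_that("a ten-channel stack yields a 10x10 matrix", {
  cv <- gen_coloc_volumes(c(24, 72, 72), rep(400, 10), rep(0.3, 9), seed = 10)
  dat <- array(0, c(10, 24, 72, 72))
  for (k in 1:10) dat[k, , , ] <- as.numeric(cv$masks[[k]]) + 0.1
  cm <- coloc_matrix(image_stack(dat, pixel_size_xy = 1, pixel_size_z = 1))
  expect_equal(dim(cm$values), c(10L, 10L))
  expect_equal(unname(cm$values), unname(cv$truth_matrix), tolerance = 1e-9)
})

test_that("delta matrices and ANOVA match closed-form expectations", {
  mk <- function(vals, roi) {
    structure(list(values = matrix(vals, 2, 2,
                                   dimnames = list(c("a", "b"), c("a", "b"))),
                   channel_names = c("a", "b"), roi_id = roi),
              class = "ColocMatrix")
  }
  # identical groups: zero delta, degenerate p, no stars
  g <- list(mk(c(100, 20, 30, 100), "r1"), mk(c(100, 22, 31, 100), "r2"),
            mk(c(100, 18, 29, 100), "r3"))
  dr0 <- delta_matrix_anova(g, g)
  expect_true(all(dr0$delta == 0))
  expect_true(all(dr0$stars == ""))
  # constructed 30-point shift, sd 5, n = 10 per group
  set.seed(33)
  g1 <- lapply(1:10, function(i) mk(c(100, rnorm(1, 40, 5), rnorm(1, 35, 5), 100),
                                    paste0("wt", i)))
  g2 <- lapply(1:10, function(i) mk(c(100, rnorm(1, 70, 5), rnorm(1, 35, 5), 100),
                                    paste0("mut", i)))
  dr <- delta_matrix_anova(g1, g2)
  # the shifted cell sits at ["b", "a"] (column-major fill of the 2x2)
  expect_equal(unname(dr$delta["b", "a"]), 30, tolerance = 5)
  expect_lt(dr$p_values["b", "a"], 0.001)
  expect_equal(unname(dr$stars["b", "a"]), "***")
  # p-values agree with the closed-form F CDF in both cells
  for (cell in list(c("b", "a"), c("a", "b"))) {
    x1 <- vapply(g1, function(m) m$values[cell[1], cell[2]], numeric(1))
    x2 <- vapply(g2, function(m) m$values[cell[1], cell[2]], numeric(1))
    expect_equal(unname(dr$p_values[cell[1], cell[2]]),
                 oracle_anova_p(x1, x2), tolerance = 1e-10)
  }
  # the study's group size (n = 3 vs 3) runs without error
  expect_s3_class(delta_matrix_anova(g1[1:3], g2[1:3]), "DeltaResult")
  expect_error(delta_matrix_anova(g1[1], g2), "at least 2")
})
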