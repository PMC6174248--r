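test_that("voxelwise entropy maps agree with the analytic white-noise mean", {
  set.seed(12)
  d <- c(4, 4, 4)
  vol <- bold4d(array(rnorm(prod(d) * 130), dim = c(d, 130)))
  st <- voxelwise_mse(vol, params = mse_params(m = 2, r = 0.35))
  m1 <- mean(st$maps$scale1, na.rm = TRUE)
  expect_lt(abs(m1 - analytic_white_noise_se(0.35)), 0.15)
  # scale 6 on 130 retained points runs on floor(130/6) = 21 samples
  expect_gt(mean(is.finite(st$maps$scale6)), 0.9)
})

test_that("scale-1 maps equal direct sample entropy on audited voxels", {
  set.seed(13)
  d <- c(5, 5, 4)
  vol <- bold4d(array(rnorm(prod(d) * 100), dim = c(d, 100)))
  # standardize voxels so the map tolerance r equals the absolute one
  flat <- matrix(as.numeric(vol$data), prod(d), 100)
  flat <- t(apply(flat, 1, standardize))
  vol$data <- array(flat, dim = c(d, 100))
  p <- mse_params(m = 2, r = 0.35)
  st <- voxelwise_mse(vol, params = p)
  for (v in sample(prod(d), 20)) {
    direct <- sample_entropy(flat[v, ], p$m, p$r)
    expect_identical(st$maps$scale1[v], direct$se)
  }
})

test_that("constant voxels are missing in every scale map and counted", {
  set.seed(14)
  d <- c(4, 4, 3)
  arr <- array(rnorm(prod(d) * 60), dim = c(d, 60))
  arr[2, 3, 1, ] <- 7
  st <- voxelwise_mse(bold4d(arr), params = mse_params(scales = 1:3))
  expect_true(all(vapply(st$maps, function(m) is.na(m[2, 3, 1]), logical(1))))
  expect_false(st$mask[2, 3, 1])
})

test_that("maps are invariant to voxel visitation order", {
  set.seed(15)
  d <- c(4, 3, 3)
  arr <- array(rnorm(prod(d) * 80), dim = c(d, 80))
  st <- voxelwise_mse(bold4d(arr), params = mse_params(scales = 1:2))
  # permute the voxel order, map, then undo the permutation
  perm <- sample(prod(d))
  flat <- matrix(as.numeric(arr), prod(d), 80)
  arr_p <- array(flat[perm, ], dim = c(d, 80))
  st_p <- voxelwise_mse(bold4d(arr_p), params = mse_params(scales = 1:2))
  for (s in 1:2) {
    back <- st_p$maps[[s]]
    unperm <- array(NA_real_, d)
    unperm[perm] <- back
    expect_identical(unperm, st$maps[[s]])
  }
})

test_that("mask means are single-voxel exact, linear under disjoint union, and monotone for white noise", {
  set.seed(16)
  d <- c(6, 6, 6)
  vol <- bold4d(array(rnorm(prod(d) * 130), dim = c(d, 130)))
  st <- voxelwise_mse(vol, params = mse_params())
  one <- array(FALSE, d); one[3, 3, 3] <- TRUE
  m_one <- mean_entropy_in_mask(st, one)
  expect_equal(unname(m_one),
               vapply(st$maps, function(m) m[3, 3, 3], numeric(1)),
               ignore_attr = TRUE)
  a <- array(FALSE, d); a[1:3, , ] <- TRUE
  b <- array(FALSE, d); b[4:6, , ] <- TRUE
  m_u <- mean_entropy_in_mask(st, a | b)
  w <- (sum(a) * mean_entropy_in_mask(st, a) +
          sum(b) * mean_entropy_in_mask(st, b)) / (sum(a) + sum(b))
  expect_equal(m_u, w, tolerance = 1e-12)
  all_mask <- array(TRUE, d)
  curve <- mean_entropy_in_mask(st, all_mask)
  expect_true(all(diff(curve) < 0))  # white-noise volume decreases with scale
  empty <- array(FALSE, d)
  expect_warning(m_e <- mean_entropy_in_mask(st, empty), "empty")
  expect_true(all(is.na(m_e)))
})

test_that("ROI spheres select exactly the voxels a brute-force scan selects", {
  d <- c(20, 24, 20)
  aff <- grid_affine(d, 3)
  center <- c(4, -7, 2)
  idx <- sphere_voxels(d, aff, center, 8)
  # exhaustive scan over every voxel center
  g <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                             z = 0:(d[3] - 1)))
  mm <- t(aff[1:3, 1:3] %*% t(g) + aff[1:3, 4])
  ref <- which(rowSums(sweep(mm, 2, center)^2) <= 64 + 1e-9)
  expect_setequal(idx, ref)
  # 8-mm sphere on a 3-mm grid: count matches the exhaustive count
  expect_identical(length(idx), length(ref))
})

test_that("sphere extraction returns single-voxel values and region constants", {
  set.seed(17)
  d <- c(8, 8, 8)
  vol <- bold4d(array(rnorm(prod(d) * 60), dim = c(d, 60)))
  st <- voxelwise_mse(vol, params = mse_params(scales = 1:2))
  aff <- st$affine
  # sub-voxel radius centered on a voxel center -> that voxel
  ctr <- drop(aff %*% c(3, 4, 2, 1))[1:3]
  v <- extract_roi_sphere(st, roi_spec("one", ctr, 1.2))
  expect_equal(unname(v), c(st$maps[[1]][4, 5, 3], st$maps[[2]][4, 5, 3]))
  # constant map region -> that constant
  st$maps[[1]][] <- 2.5
  v2 <- extract_roi_sphere(st, roi_spec("const", ctr, 6))
  expect_identical(unname(v2[1]), 2.5)
  expect_error(extract_roi_sphere(st, roi_spec("out", c(999, 0, 0), 2)),
               "does not intersect")
})

test_that("the nine study peak coordinates give non-empty 8-mm spheres on an MNI-like grid", {
  d <- c(61, 73, 61)
  aff <- diag(c(3, 3, 3, 1))
  aff[1:3, 4] <- c(-90, -126, -72)
  peaks <- rbind(c(0, -9, 0), c(-18, 54, 42), c(15, -51, -9),
                 c(33, -12, 6), c(60, -18, 0), c(-66, -18, -3),
                 c(6, 21, -12), c(-54, -69, -9), c(60, -33, 27))
  for (i in seq_len(nrow(peaks))) {
    expect_gt(length(sphere_voxels(d, aff, peaks[i, ], 8)), 0)
  }
})
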