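test_that("ROI crop and coronal downsampling produce the documented shape", {
  set.seed(1)
  g <- grid_spec(c(359L, 287L, 153L), 0.25)
  vol <- recon_volume(array(runif(prod(g$shape)), dim = g$shape), g)
  out <- crop_and_downsample(vol)
  expect_identical(out$grid$shape, c(155L, 155L, 128L))
  expect_equal(out$grid$pitch, c(0.5, 0.5, 0.25))
  expect_error(crop_and_downsample(array(0, c(100, 100, 100))), "smaller")
})

test_that("bicubic downsampling preserves constants and inverts smooth upsampling", {
  cv <- array(4.2, dim = c(64L, 64L, 8L))
  out <- crop_and_downsample(cv, crop_shape = c(64L, 64L, 8L))
  expect_lt(max(abs(out$values - 4.2)), 1e-6)

  # smooth volume, exactly 2x-upsampled (pixel-center convention) then
  # downsampled, returns near itself
  n <- 32L
  xs <- seq(0, 2 * pi, length.out = n)
  base <- outer(outer(sin(xs) + 1.5, cos(xs / 2) + 1.5), rep(1, 4))
  fine <- (seq_len(2 * n) - 0.5) / 2 + 0.5  # fine pixel centers in coarse coords
  smooth_up <- array(0, dim = c(2 * n, 2 * n, 4))
  for (z in 1:4) {
    m <- base[, , z]
    mi <- apply(m, 2, function(v) stats::spline(1:n, v, xout = fine)$y)
    smooth_up[, , z] <- t(apply(mi, 1, function(v) stats::spline(1:n, v, xout = fine)$y))
  }
  down <- crop_and_downsample(smooth_up, crop_shape = c(2L * n, 2L * n, 4L))
  rms <- sqrt(mean((down$values - base)^2)) / sqrt(mean(base^2))
  expect_lt(rms, 0.01)
})

test_that("pair normalization maps the dense range to [0,1] with a shared scale", {
  set.seed(2)
  d <- array(rnorm(8^3), dim = c(8, 8, 8))
  s <- 0.25 * d + 0.1
  pr <- normalize_pair(s, d)
  expect_equal(range(pr$dense), c(0, 1))
  expect_equal(pr$sparse, (s - min(d)) / diff(range(d)))
})

test_that("random training patches stay in bounds, align, and are deterministic", {
  set.seed(3)
  d <- array(runif(40 * 36 * 32), dim = c(40, 36, 32))
  pr <- as_pair(0.5 * d, d)
  p1 <- random_training_patch(pr, seed = 9, patch = 16)
  p2 <- random_training_patch(pr, seed = 9, patch = 16)
  expect_identical(p1, p2)
  expect_equal(p1$sparse, 0.5 * p1$dense)  # same window and flips on both members
  for (k in 1:200) {
    p <- random_training_patch(pr, seed = k, patch = 16)
    expect_true(all(p$corner >= 0 & p$corner + 16 <= dim(d)))
  }
  p0 <- random_training_patch(pr, seed = 1, patch = 16, flip_prob = 0)
  co <- p0$corner
  expect_equal(p0$dense, d[co[1] + 1:16, co[2] + 1:16, co[3] + 1:16])
  expect_error(random_training_patch(pr, 1, patch = 64), "below the patch")
})

test_that("tiling covers every voxel with flush boundary patches", {
  v <- array(runif(155 * 155 * 128), dim = c(155, 155, 128))
  ps <- tile_volume(v, patch = 96, overlap = 37)
  expect_equal(length(ps$patches), 8)  # 2 x 2 x 2
  cover <- array(0L, dim = dim(v))
  for (i in seq_along(ps$patches)) {
    co <- ps$corners[i, ]
    cover[co[1] + 1:96, co[2] + 1:96, co[3] + 1:96] <-
      cover[co[1] + 1:96, co[2] + 1:96, co[3] + 1:96] + 1L
  }
  expect_true(all(cover >= 1L))
  expect_true(all(ps$corners >= 0 &
                    sweep(ps$corners, 2, dim(v) - 96L) <= 0))

  one <- tile_volume(array(0, c(96, 96, 96)), patch = 96)
  expect_equal(length(one$patches), 1)
  expect_error(tile_volume(v, patch = 96, overlap = 96), "overlap")
  expect_error(tile_volume(array(0, c(50, 50, 50)), patch = 96), "below the patch")
})

test_that("Gaussian stitching is the identity on an unmodified tiling", {
  set.seed(4)
  v <- array(runif(60 * 52 * 44), dim = c(60, 52, 44))
  ps <- tile_volume(v, patch = 32, overlap = 10)
  expect_lt(max(abs(stitch_gaussian(ps) - v)), 1e-6)

  single <- tile_volume(v[1:32, 1:32, 1:32], patch = 32)
  expect_equal(stitch_gaussian(single), v[1:32, 1:32, 1:32])
})

test_that("stitched overlaps are convex combinations of the patch values", {
  ps <- tile_volume(array(0, c(48, 32, 32)), patch = 32, overlap = 16)
  expect_equal(length(ps$patches), 2)
  ps$patches[[1]][] <- 1
  ps$patches[[2]][] <- 3
  st <- stitch_gaussian(ps)
  ov <- st[17:32, , ]  # overlap region
  expect_true(all(ov > 1 & ov < 3))
  expect_equal(st[1:16, , ], array(1, c(16, 32, 32)))
  expect_equal(st[33:48, , ], array(3, c(16, 32, 32)))
})
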