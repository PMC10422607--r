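test_that("low-pass filter has unit DC gain and attenuates out-of-band tones", {
  dc <- tone_channels(1e6); dc$signals[] <- 1
  expect_lt(max(abs(lowpass_filter(dc, 4e6)$signals - 1)), 1e-6)
  tone <- tone_channels(8e6)
  att <- fft_amplitude(lowpass_filter(tone, 4e6), 8e6) / fft_amplitude(tone, 8e6)
  expect_lt(20 * log10(att), -20)
  zero <- tone_channels(1e6); zero$signals[] <- 0
  expect_true(all(lowpass_filter(zero, 4e6)$signals == 0))
  expect_error(lowpass_filter(tone, 12e6), "Nyquist")
})

test_that("delay-and-sum equals a brute-force triple loop", {
  g <- grid_spec(c(16L, 16L, 16L), 0.5)
  geom <- test_array(32, g)
  set.seed(5)
  p0 <- point_source(g, c(8L, 8L, 8L))
  p0$p0 <- array(runif(16^3), dim = g$shape)
  cd <- forward_project(p0, geom)
  rec <- das_reconstruct(cd, g)
  fs <- cd$timing$fs
  naive <- array(0, dim = g$shape)
  for (z in 1:16) for (y in 1:16) for (x in 1:16) {
    pv <- (g$origin + (c(x, y, z) - 1) * g$pitch) / 1000
    dd <- sqrt(colSums((t(geom$positions) - pv)^2))
    ti <- dd / 1500 * fs
    i0 <- floor(ti); fr <- ti - i0
    naive[x, y, z] <- sum(cd$signals[cbind(1:32, i0 + 1)] * (1 - fr) +
                          cd$signals[cbind(1:32, i0 + 2)] * fr)
  }
  expect_lt(max(abs(naive - rec$values)) / max(abs(naive)), 1e-9)

  # all-zero channel data reconstructs to zero
  cd0 <- cd; cd0$signals[] <- 0
  expect_true(all(das_reconstruct(cd0, g)$values == 0))
})

test_that("delay-and-sum is linear in the channel data", {
  g <- grid_spec(c(16L, 16L, 16L), 0.5)
  geom <- test_array(16, g)
  cd1 <- forward_project(point_source(g, c(6L, 8L, 10L)), geom)
  cd2 <- cd1
  set.seed(6)
  cd2$signals <- matrix(rnorm(length(cd1$signals)), nrow(cd1$signals))
  mix <- cd1; mix$signals <- 2 * cd1$signals - 0.5 * cd2$signals
  r <- das_reconstruct(mix, g)$values
  r12 <- 2 * das_reconstruct(cd1, g)$values - 0.5 * das_reconstruct(cd2, g)$values
  expect_lt(max(abs(r - r12)) / max(abs(r12)), 1e-9)
})

test_that("point source localizes to its voxel through forward model plus DAS", {
  g <- grid_spec(c(64L, 64L, 64L), 0.5)
  geom <- test_array(256, g)
  src <- c(30L, 36L, 40L)
  cd <- forward_project(point_source(g, src), geom)
  cd <- lowpass_filter(apply_transducer_response(cd), 4e6)
  rec <- das_reconstruct(cd, g)
  mx <- arrayInd(which.max(rec$values), g$shape)
  expect_lte(max(abs(mx - src)), 1)
})

test_that("two separated point sources resolve into two local maxima", {
  g <- grid_spec(c(48L, 48L, 48L), 0.5)
  geom <- test_array(512, g)
  p0 <- point_source(g, c(20L, 24L, 24L))
  p0$p0[28, 24, 24] <- 1   # 8 voxels apart along x
  cd <- lowpass_filter(apply_transducer_response(forward_project(p0, geom)), 4e6)
  v <- das_reconstruct(cd, g)$values
  prof <- v[, 24, 24]
  locmax <- which(diff(sign(diff(prof))) == -2) + 1
  peaks <- locmax[prof[locmax] > 0.5 * max(prof)]
  expect_equal(length(peaks), 2)
  expect_lt(max(abs(sort(peaks) - c(20, 28))), 2)
})

test_that("artifact energy outside the source support shrinks with more elements", {
  g <- grid_spec(c(32L, 32L, 32L), 0.5)
  geom <- test_array(512, g)
  src <- c(16L, 16L, 20L)
  cd_full <- lowpass_filter(apply_transducer_response(
    forward_project(point_source(g, src), geom)), 4e6)
  support <- array(FALSE, dim = g$shape)
  support[(src[1] - 3):(src[1] + 3), (src[2] - 3):(src[2] + 3),
          (src[3] - 3):(src[3] + 3)] <- TRUE
  art <- function(count) {
    sub <- subsample_equidistant(geom, count)
    cds <- structure(list(signals = cd_full$signals[sub$parent_indices, ],
                          timing = cd_full$timing, geometry = sub,
                          medium = cd_full$medium), class = "channel_data")
    v <- das_reconstruct(cds, g)$values
    v <- v / max(abs(v))
    sum(v[!support]^2)
  }
  a <- vapply(c(32L, 128L, 512L), art, numeric(1))
  expect_true(all(diff(a) <= 0.05 * a[-length(a)]))
})

test_that("reconstruction volumes round-trip through NIfTI", {
  g <- grid_spec(c(16L, 16L, 16L), 0.5)
  vol <- das_reconstruct(forward_project(point_source(g, c(8L, 8L, 8L)),
                                         test_array(8, g)), g)
  path <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(c(path, paste0(path, ".yaml"))), add = TRUE)
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$values, vol$values, tolerance = 1e-6)
  expect_equal(back$provenance$elements, 8)
})
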