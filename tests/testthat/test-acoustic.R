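test_that("hemisphere array has on-sphere, one-sided, quasi-uniform elements", {
  geom <- make_hemisphere_array(5120, 0.048)
  d <- sqrt(rowSums(sweep(geom$positions, 2, geom$center)^2))
  expect_lt(max(abs(d - 0.048)) / 0.048, 1e-9)
  expect_true(all(geom$positions[, 3] > geom$center[3]))
  # coefficient of variation of nearest-neighbor spacing
  set.seed(1)
  P <- geom$positions
  nn <- vapply(sample(nrow(P), 500), function(i) {
    dd <- sqrt(colSums((t(P) - P[i, ])^2))
    min(dd[dd > 0])
  }, numeric(1))
  expect_lt(stats::sd(nn) / mean(nn), 0.15)

  one <- make_hemisphere_array(1, 0.048)
  expect_equal(as.numeric(one$positions), c(0, 0, 0.048), tolerance = 1e-6)
  expect_error(make_hemisphere_array(10, -1), "radius")
})

test_that("equidistant sub-sampling strides the spiral ordering and nests", {
  geom <- make_hemisphere_array(5120, 0.048)
  s256 <- subsample_equidistant(geom, 256)
  expect_equal(nrow(s256$positions), 256)
  expect_equal(unique(diff(s256$parent_indices)), 20)
  s512 <- subsample_equidistant(geom, 512)
  expect_true(all((s512$parent_indices - 1) %% 10 == 0))
  # nesting: sub-sampling a sub-array stays within the parent's elements
  s128 <- subsample_equidistant(s256, 128)
  expect_true(all(s128$parent_indices %in% s256$parent_indices))
  idn <- subsample_equidistant(geom, 5120)
  expect_equal(idn$positions, geom$positions)
  expect_error(subsample_equidistant(geom, 0), "count")
  expect_error(subsample_equidistant(geom, 6000), "count")
})

test_that("forward projection places the bipolar transient at the travel time", {
  g <- grid_spec(c(64L, 64L, 64L), 0.5)
  geom <- test_array(64, g)
  src <- c(30L, 36L, 40L)
  cd <- forward_project(point_source(g, src), geom)
  spos <- (g$origin + (src - 1) * g$pitch) / 1000
  for (e in c(1L, 32L)) {
    d <- sqrt(sum((spos - geom$positions[e, ])^2))
    expected <- d / 1500 * cd$timing$fs
    tr <- cd$signals[e, ]
    lobes <- c(which.max(tr), which.min(tr))
    expect_lt(abs(mean(lobes) - 1 - expected), 1.5)  # center within ~1 sample
  }
  # zero source -> zero traces
  zero <- point_source(g, src); zero$p0[] <- 0
  expect_true(all(forward_project(zero, geom)$signals == 0))
})

test_that("forward projection is linear and amplitude falls off as 1/r", {
  g <- grid_spec(c(32L, 32L, 32L), 0.5)
  geom <- test_array(16, g)
  set.seed(3)
  pa <- point_source(g, c(10L, 16L, 20L)); pa$p0[5, 5, 5] <- 0.7
  pb <- point_source(g, c(20L, 12L, 8L))
  psum <- pa; psum$p0 <- pa$p0 + pb$p0
  timing <- default_timing(g, geom)
  fa <- forward_project(pa, geom, timing = timing)$signals
  fb <- forward_project(pb, geom, timing = timing)$signals
  fs <- forward_project(psum, geom, timing = timing)$signals
  expect_lt(max(abs(fs - (fa + fb))) / max(abs(fs)), 1e-9)

  # fixed source, increasing distance: pre-filter peak amplitude ~ 1/r
  ctr <- c(16L, 16L, 28L)
  cd1 <- forward_project(point_source(g, ctr), geom, timing = timing)
  e <- 1L
  d1 <- sqrt(sum(((g$origin + (ctr - 1) * g$pitch) / 1000 - geom$positions[e, ])^2))
  ctr2 <- c(16L, 16L, 6L)
  cd2 <- forward_project(point_source(g, ctr2), geom, timing = timing)
  d2 <- sqrt(sum(((g$origin + (ctr2 - 1) * g$pitch) / 1000 - geom$positions[e, ])^2))
  a1 <- max(abs(cd1$signals[e, ])); a2 <- max(abs(cd2$signals[e, ]))
  expect_gt(d2, d1)
  expect_lt(a2, a1)

  # translating the source one voxel toward the element advances the transient
  ctr3 <- ctr + c(0L, 0L, 2L)  # closer to the bowl pole
  cd3 <- forward_project(point_source(g, ctr3), geom, timing = timing)
  pole <- which.max(geom$positions[, 3])
  t_orig <- which.max(abs(cd1$signals[pole, ]))
  t_shift <- which.max(abs(cd3$signals[pole, ]))
  adv <- (t_orig - t_shift) * 1 / cd1$timing$fs
  expect_lt(abs(adv - 2 * g$pitch[3] / 1000 / 1500), 1.5 / cd1$timing$fs)

  # too-short record errors with the required length
  expect_error(forward_project(pa, geom, timing = timing_spec(20e6, 50L)),
               "n_samples")
})

test_that("transducer response is a unit-gain zero-phase band-pass with -6 dB points", {
  f0 <- 2.5e6
  r0 <- fft_amplitude(apply_transducer_response(tone_channels(f0)), f0) /
    fft_amplitude(tone_channels(f0), f0)
  expect_lt(abs(r0 - 1), 0.01)
  fl <- f0 * (1 - 0.35)
  rl <- fft_amplitude(apply_transducer_response(tone_channels(fl)), fl) /
    fft_amplitude(tone_channels(fl), fl)
  expect_lt(abs(r0 / rl - 2), 0.02)
  fh <- f0 * (1 + 0.35)
  rh <- fft_amplitude(apply_transducer_response(tone_channels(fh)), fh) /
    fft_amplitude(tone_channels(fh), fh)
  expect_lt(abs(r0 / rh - 2), 0.02)

  zero <- tone_channels(f0); zero$signals[] <- 0
  expect_true(all(apply_transducer_response(zero)$signals == 0))
  expect_error(apply_transducer_response(tone_channels(f0), f0 = 11e6), "Nyquist")
})

test_that("additive noise hits the requested SNR and is seed-deterministic", {
  cd <- tone_channels(1e6, nt = 65536L)
  expect_identical(add_noise(cd, Inf, 1), cd)
  n1 <- add_noise(cd, 20, seed = 4)
  n2 <- add_noise(cd, 20, seed = 4)
  expect_identical(n1$signals, n2$signals)
  snr <- 10 * log10(mean(cd$signals^2) / mean((n1$signals - cd$signals)^2))
  expect_lt(abs(snr - 20), 0.5)
  zero <- cd; zero$signals[] <- 0
  expect_error(add_noise(zero, 20, 1), "all-zero")
})

test_that("channel data round-trips through serialization", {
  g <- grid_spec(c(16L, 16L, 16L), 0.5)
  geom <- test_array(8, g)
  cd <- forward_project(point_source(g, c(8L, 8L, 8L)), geom)
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(c(path, paste0(path, ".yaml"))), add = TRUE)
  write_channel_data(cd, path)
  back <- read_channel_data(path)
  expect_identical(back$signals, cd$signals)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  expect_equal(meta$fs, cd$timing$fs)
})
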