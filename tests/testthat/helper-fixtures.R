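# shared fixtures, all generated in code

# small phantom configuration used across tests
small_grid <- function() grid_spec(c(80L, 80L, 48L), 0.5)

small_params <- function(...) {
  args <- utils::modifyList(list(semi_axes = c(14, 13, 14), skin_thickness = 1.5,
                                 vessel_depth = 4L, vessel_root_diameter = 2,
                                 n_fibers = 6L, muscle_thickness = 2),
                            list(...))
  do.call(phantom_params, args)
}

# blobby synthetic "dense" patch: a few bright spheres on zero background
blob_patch <- function(seed, n = 24L, k = 5L) {
  set.seed(seed)
  a <- array(0, c(n, n, n))
  for (i in seq_len(k)) {
    c0 <- stats::runif(3, 6, n - 6)
    r <- stats::runif(1, 2, 4)
    d2 <- outer(outer((seq_len(n) - c0[1])^2, (seq_len(n) - c0[2])^2, "+"),
                (seq_len(n) - c0[3])^2, "+")
    a[d2 <= r^2] <- stats::runif(1, 0.5, 1)
  }
  a
}

as_pair <- function(sparse, dense) {
  structure(list(sparse = sparse, dense = dense, grid = NULL),
            class = "paired_volume")
}

# a centered hemispherical array over a grid, mirroring the imaging geometry
test_array <- function(n, grid, radius = 0.048) {
  ext <- grid$shape * grid$pitch
  make_hemisphere_array(n, radius, c(ext[1] / 2, ext[2] / 2, 2) / 1000)
}

point_source <- function(grid, idx) {
  p0 <- array(0, dim = grid$shape)
  p0[idx[1], idx[2], idx[3]] <- 1
  structure(list(p0 = p0, grid = grid), class = "initial_pressure")
}

# single-trace channel-data container for filter tests
tone_channels <- function(f, fs = 20e6, nt = 4096L) {
  tt <- (seq_len(nt) - 1) / fs
  structure(list(signals = matrix(sin(2 * pi * f * tt), 1),
                 timing = timing_spec(fs, nt),
                 geometry = NULL, medium = medium_spec()),
            class = "channel_data")
}

fft_amplitude <- function(cd, f) {
  nt <- ncol(cd$signals)
  abs(stats::fft(cd$signals[1, ]))[round(f / cd$timing$fs * nt) + 1]
}
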