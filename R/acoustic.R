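#' Hemispherical transducer array
#'
#' Places n elements quasi-uniformly on a hemisphere using a Fibonacci
#' spiral lattice restricted to one side of the equatorial plane. The
#' spiral index (pole outward) is the canonical element ordering used by
#' [subsample_equidistant()].
#'
#' @param n number of elements.
#' @param radius hemisphere radius in meters.
#' @param center hemisphere center (meters).
#' @param orientation +1 places the bowl on the +z side of the center,
#'   -1 on the -z side.
#' @return an object of class `array_geometry` with fields `positions`
#'   (n x 3, meters), `radius`, `center`, `index` (canonical spiral order)
#'   and `parent_indices` (NULL for a full array).
#' @export
make_hemisphere_array <- function(n, radius = 0.048, center = c(0, 0, 0),
                                  orientation = 1L) {
  if (radius <= 0) stopf("radius must be positive")
  n <- as.integer(n)
  if (n < 1L) stopf("n must be >= 1")
  i <- seq_len(n) - 1L
  # heights in (0,1]: strictly one side of the equator; a single element
  # sits at the pole
  h <- if (n == 1L) 1 else 1 - (i + 0.5) / n
  rho <- sqrt(pmax(0, 1 - h^2))
  ga <- pi * (3 - sqrt(5))          # golden angle
  pos <- cbind(center[1] + radius * rho * cos(i * ga),
               center[2] + radius * rho * sin(i * ga),
               center[3] + radius * orientation * h)
  structure(list(positions = pos, radius = radius, center = as.numeric(center),
                 index = seq_len(n), parent_indices = NULL,
                 orientation = as.integer(orientation)),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("array_geometry: %d elements on a hemisphere, R = %.3g m\n",
              nrow(x$positions), x$radius))
  invisible(x)
}

#' Equidistant element under-sampling
#'
#' Selects `count` elements at uniform stride along the canonical spiral
#' ordering (e.g. 256 of 5120 selects every 20th element). Deterministic;
#' the selected parent indices are recorded.
#'
#' @param geom an `array_geometry`.
#' @param count number of elements to keep, between 1 and n.
#' @return an `array_geometry` with `parent_indices` set.
#' @export
subsample_equidistant <- function(geom, count) {
  n <- nrow(geom$positions)
  count <- as.integer(count)
  if (count < 1L || count > n) stopf("count must be in [1, %d]", n)
  sel <- round((seq_len(count) - 1L) * n / count) + 1L
  out <- geom
  out$positions <- geom$positions[sel, , drop = FALSE]
  out$index <- seq_len(count)
  out$parent_indices <- if (is.null(geom$parent_indices)) sel else geom$parent_indices[sel]
  out
}

#' Acoustic medium specification
#'
#' Homogeneous, lossless medium.
#' @param c speed of sound (m/s).
#' @return object of class `medium_spec`.
#' @export
medium_spec <- function(c = 1500) {
  if (c <= 0) stopf("speed of sound must be positive")
  structure(list(c = c), class = "medium_spec")
}

#' Sampling specification for channel data
#'
#' @param fs sampling rate (Hz).
#' @param n_samples record length in samples.
#' @param t0 time of the first sample (s).
#' @return object of class `timing_spec`.
#' @export
timing_spec <- function(fs = 20e6, n_samples, t0 = 0) {
  if (fs <= 0 || n_samples < 2) stopf("invalid timing spec")
  structure(list(fs = fs, n_samples = as.integer(n_samples), t0 = t0),
            class = "timing_spec")
}

# voxel centers of a grid in meters, as a 3 x nvox matrix
grid_centers_m <- function(grid) {
  xs <- axis_centers(grid, 1); ys <- axis_centers(grid, 2); zs <- axis_centers(grid, 3)
  shp <- grid$shape
  rbind(rep(xs, times = shp[2] * shp[3]),
        rep(rep(ys, each = shp[1]), times = shp[3]),
        rep(zs, each = shp[1] * shp[2])) / 1000
}

required_samples <- function(grid, geom, medium, fs, t0) {
  ext <- grid_extent(grid) / 1000
  org <- grid$origin / 1000
  corners <- as.matrix(expand.grid(c(org[1], org[1] + ext[1]),
                                   c(org[2], org[2] + ext[2]),
                                   c(org[3], org[3] + ext[3])))
  dmax <- 0
  for (i in seq_len(nrow(corners)))
    dmax <- max(dmax, sqrt(colSums((t(geom$positions) - corners[i, ])^2)))
  as.integer(ceiling((dmax / medium$c - t0) * fs) + 4L)
}

#' Default timing for a grid/array pair
#'
#' Chooses a record long enough to cover the farthest voxel-to-element
#' travel time at the given sampling rate.
#' @param grid a [grid_spec()].
#' @param geom an `array_geometry`.
#' @param medium a [medium_spec()].
#' @param fs sampling rate (Hz).
#' @param t0 start time (s).
#' @return a [timing_spec()].
#' @export
default_timing <- function(grid, geom, medium = medium_spec(), fs = 20e6, t0 = 0) {
  timing_spec(fs, required_samples(grid, geom, medium, fs, t0), t0)
}

#' Forward-project initial pressure to channel data
#'
#' Exact homogeneous-lossless-medium solution for ideal point detectors:
#' source voxels are binned by arrival time t = |r_voxel - r_elem|/c with
#' weight p0/(4 pi |r_voxel - r_elem|), then the time derivative is taken.
#' Linear in p0.
#'
#' @param p0 an `initial_pressure`.
#' @param geom an `array_geometry`.
#' @param medium a [medium_spec()].
#' @param timing a [timing_spec()]; `NULL` chooses [default_timing()].
#' @return an object of class `channel_data` with fields `signals`
#'   (n_elements x n_samples), `timing`, `geometry`, `medium`.
#' @export
forward_project <- function(p0, geom, medium = medium_spec(), timing = NULL) {
  timing <- timing %||% default_timing(p0$grid, geom, medium)
  need <- required_samples(p0$grid, geom, medium, timing$fs, timing$t0)
  if (timing$n_samples < need)
    stopf("timing window too short: need n_samples >= %d, got %d", need, timing$n_samples)
  nz <- which(p0$p0 != 0)
  if (length(nz)) {
    pos <- grid_centers_m(p0$grid)[, nz, drop = FALSE]
    sig <- cpp_forward_project(pos, as.numeric(p0$p0[nz]), t(geom$positions),
                               medium$c, timing$fs, timing$t0, timing$n_samples)
  } else {
    sig <- matrix(0, nrow(geom$positions), timing$n_samples)
  }
  structure(list(signals = sig, timing = timing, geometry = geom, medium = medium),
            class = "channel_data")
}

#' @export
print.channel_data <- function(x, ...) {
  cat(sprintf("channel_data: %d elements x %d samples @ %.3g MHz\n",
              nrow(x$signals), ncol(x$signals), x$timing$fs / 1e6))
  invisible(x)
}

# Keep only the rows of a channel-data set belonging to a sub-array whose
# parent_indices refer to cd's geometry. Valid because elements are
# independent in the forward model.
subset_channels <- function(cd, sub_geom) {
  sel <- sub_geom$parent_indices
  if (is.null(sel)) stopf("sub-array carries no parent indices")
  structure(list(signals = cd$signals[sel, , drop = FALSE], timing = cd$timing,
                 geometry = sub_geom, medium = cd$medium), class = "channel_data")
}

# apply a zero-phase magnitude response H(|f|) along the time axis
apply_freq_response <- function(signals, fs, hfun) {
  nt <- ncol(signals)
  f <- (seq_len(nt) - 1) / nt * fs
  f <- pmin(f, fs - f)
  H <- hfun(f)
  ft <- stats::mvfft(t(signals))
  Re(stats::mvfft(ft * H, inverse = TRUE)) / nt
}

#' Band-limit channel data with the transducer response
#'
#' Zero-phase Gaussian band-pass with unit gain at the central frequency f0
#' and -6 dB (half amplitude) at f0*(1 +/- fractional_bw/2).
#'
#' @param cd a `channel_data`.
#' @param f0 central frequency (Hz).
#' @param fractional_bw fractional -6 dB bandwidth (0.7 = 70 percent).
#' @return band-limited `channel_data`.
#' @export
apply_transducer_response <- function(cd, f0 = 2.5e6, fractional_bw = 0.7) {
  fs <- cd$timing$fs
  if (f0 >= fs / 2) stopf("f0 must be below the Nyquist frequency %g", fs / 2)
  sigma <- (f0 * fractional_bw / 2) / sqrt(2 * log(2))
  out <- cd
  out$signals <- t(apply_freq_response(cd$signals, fs,
                                       function(f) exp(-(f - f0)^2 / (2 * sigma^2))))
  out
}

#' Add white Gaussian noise at a target SNR
#'
#' @param cd a `channel_data`.
#' @param snr_db target signal-to-noise ratio in dB; `Inf` returns the
#'   input unchanged.
#' @param seed integer seed (deterministic output).
#' @return noisy `channel_data`.
#' @export
add_noise <- function(cd, snr_db, seed) {
  if (is.infinite(snr_db)) return(cd)
  rms <- sqrt(mean(cd$signals^2))
  if (rms == 0) stopf("cannot set a finite SNR on all-zero signals")
  sigma <- rms / 10^(snr_db / 20)
  out <- cd
  out$signals <- cd$signals + with_seed(seed, {
    matrix(stats::rnorm(length(cd$signals), sd = sigma), nrow(cd$signals))
  })
  out
}
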