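#' Zero-phase low-pass filter for channel data
#'
#' Butterworth-magnitude zero-phase low-pass (applied in the frequency
#' domain, so no group delay), with unit DC gain.
#'
#' @param cd a `channel_data`.
#' @param cutoff -3 dB cutoff frequency (Hz); must be below Nyquist.
#' @param order filter order; attenuation at 2x cutoff is about 6*order dB.
#' @return filtered `channel_data`.
#' @export
lowpass_filter <- function(cd, cutoff = 4e6, order = 4L) {
  fs <- cd$timing$fs
  if (cutoff >= fs / 2) stopf("cutoff must be below the Nyquist frequency %g", fs / 2)
  out <- cd
  out$signals <- t(apply_freq_response(cd$signals, fs,
                                       function(f) 1 / sqrt(1 + (f / cutoff)^(2 * order))))
  out
}

#' 3D delay-and-sum reconstruction
#'
#' Plain unweighted delay-and-sum on a Cartesian grid: each voxel value is
#' the sum over elements of the signal at the voxel-specific time of flight
#' |r_voxel - r_elem|/c, with linear interpolation between samples. No
#' apodization; negative values are retained (photoacoustic transients are
#' bipolar). Linear in the channel data.
#'
#' @param cd a `channel_data`.
#' @param grid the reconstruction [grid_spec()] (cubic voxels, mm).
#' @param medium a [medium_spec()]; defaults to the one in `cd`.
#' @return an object of class `recon_volume` with fields `values` (3D
#'   array), `grid`, and `provenance` (list with `kind`, `elements`).
#' @export
das_reconstruct <- function(cd, grid, medium = NULL) {
  medium <- medium %||% cd$medium
  if (length(unique(grid$pitch)) != 1L) stopf("delay-and-sum requires cubic voxels")
  vals <- cpp_das(t(cd$signals), t(cd$geometry$positions),
                  grid$origin / 1000, grid$pitch[1] / 1000, grid$shape,
                  medium$c, cd$timing$fs, cd$timing$t0)
  structure(list(values = array(vals, dim = grid$shape), grid = grid,
                 provenance = list(kind = "das", elements = nrow(cd$signals))),
            class = "recon_volume")
}

recon_volume <- function(values, grid, provenance = list(kind = "unknown", elements = NA)) {
  structure(list(values = values, grid = grid, provenance = provenance),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  cat(sprintf("recon_volume [%s, %s elements]: ", x$provenance$kind,
              as.character(x$provenance$elements)))
  print(x$grid)
  invisible(x)
}
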