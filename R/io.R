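#' Write a labeled phantom as NIfTI
#'
#' The integer label volume is stored with the voxel pitch in the header;
#' the generation parameters go to a YAML sidecar (`<path>.yaml`).
#'
#' @param vol a `tissue_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_phantom <- function(vol, path) {
  img <- RNifti::asNifti(vol$labels)
  RNifti::pixdim(img) <- vol$grid$pitch
  RNifti::writeNifti(img, path)
  meta <- list(seed = vol$seed, params = unclass(vol$params),
               grid = list(shape = vol$grid$shape, pitch = vol$grid$pitch,
                           origin = vol$grid$origin))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a phantom written by [write_phantom()]
#' @param path NIfTI path.
#' @return a `tissue_volume`.
#' @export
read_phantom <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  g <- grid_spec(meta$grid$shape, meta$grid$pitch, meta$grid$origin)
  structure(list(grid = g, labels = array(as.integer(img), dim = dim(img)),
                 seed = meta$seed, params = do.call(phantom_params, meta$params)),
            class = "tissue_volume")
}

#' Write a scalar volume as NIfTI
#'
#' Works for `recon_volume`s (provenance goes to a YAML sidecar) and for
#' the grids of an `optical_result`.
#'
#' @param vol `recon_volume` or 3D array.
#' @param path output path.
#' @param grid [grid_spec()] when `vol` is a plain array.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, grid = NULL) {
  v <- as_values(vol)
  g <- if (inherits(vol, "recon_volume")) vol$grid else grid
  img <- RNifti::asNifti(v)
  if (!is.null(g)) RNifti::pixdim(img) <- g$pitch
  RNifti::writeNifti(img, path)
  if (inherits(vol, "recon_volume"))
    yaml::write_yaml(list(provenance = vol$provenance,
                          grid = list(shape = g$shape, pitch = g$pitch,
                                      origin = g$origin)),
                     paste0(path, ".yaml"))
  invisible(path)
}

#' Read a volume written by [write_volume()]
#' @param path NIfTI path.
#' @return a `recon_volume` (unit grid if no sidecar is present).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  v <- array(as.numeric(img), dim = dim(img))
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    g <- grid_spec(meta$grid$shape, meta$grid$pitch, meta$grid$origin)
    recon_volume(v, g, meta$provenance)
  } else {
    recon_volume(v, grid_spec(dim(v), RNifti::pixdim(img)[1:3]))
  }
}

#' Serialize channel data
#'
#' Stores the per-element signal matrix with its timing, geometry and
#' medium in R's native serialization, plus a YAML sidecar with the
#' acquisition metadata (fs, t0, c, radius, element count, parent
#' indices).
#'
#' @param cd a `channel_data`.
#' @param path output path (`.rds`).
#' @return the path, invisibly.
#' @export
write_channel_data <- function(cd, path) {
  saveRDS(cd, path)
  yaml::write_yaml(list(n_elements = nrow(cd$signals), n_samples = ncol(cd$signals),
                        fs = cd$timing$fs, t0 = cd$timing$t0, c = cd$medium$c,
                        radius = cd$geometry$radius,
                        parent_indices = cd$geometry$parent_indices),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read channel data written by [write_channel_data()]
#' @param path `.rds` path.
#' @return a `channel_data`.
#' @export
read_channel_data <- function(path) readRDS(path)

#' Write a sweep report as CSV and JSON
#' @param report a `sweep_report`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return the report, invisibly.
#' @export
write_sweep_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) utils::write.csv(report, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, dataframe = "rows", digits = NA)
  invisible(report)
}

#' Save / load a trained network
#'
#' Single-file checkpoint embedding the model configuration, weights and
#' training history.
#' @param fit a `resunet_fit` or `res_unet`.
#' @param path checkpoint path (`.rds`).
#' @return the path ([save_checkpoint()]) / the restored object
#'   ([load_checkpoint()]).
#' @export
save_checkpoint <- function(fit, path) { saveRDS(fit, path); invisible(path) }

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
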