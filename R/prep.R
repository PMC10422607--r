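as_values <- function(vol) if (inherits(vol, "recon_volume")) vol$values else vol

#' Crop to the region of interest and downsample the coronal plane
#'
#' Crops the volume to `crop_shape` voxels about the region of interest
#' (by default centered on the volume's intensity centroid), then reduces
#' the number of voxels in the coronal (x-y) plane by `down` times with
#' antialiased bicubic interpolation. The axial (z) sampling is unchanged,
#' so the default 310 x 310 x 128 crop becomes 155 x 155 x 128.
#'
#' If the volume is shorter than the crop along an axis (the default
#' simulation grid is 287 voxels along y against a 310-voxel crop), the
#' crop window is zero-padded symmetrically on that axis; a volume shorter
#' than half the crop on any axis is an error.
#'
#' @param vol a `recon_volume` (or plain 3D array with `grid = NULL`).
#' @param crop_shape integer length-3 crop size in voxels.
#' @param center voxel index (1-based, length 3) of the ROI center; `NULL`
#'   uses the centroid of |values|.
#' @param down in-plane downsampling factor.
#' @return a `recon_volume` on the cropped, downsampled grid (in-plane
#'   pitch multiplied by `down`).
#' @export
crop_and_downsample <- function(vol, crop_shape = c(310L, 310L, 128L),
                                center = NULL, down = 2L) {
  v <- as_values(vol)
  shp <- dim(v)
  crop_shape <- as.integer(crop_shape)
  if (any(shp < crop_shape %/% 2L))
    stopf("input (%s) smaller than the crop (%s)", paste(shp, collapse = "x"),
          paste(crop_shape, collapse = "x"))
  if (is.null(center)) {
    w <- abs(v)
    tot <- sum(w)
    center <- if (tot > 0) {
      c(sum(apply(w, 1, sum) * seq_len(shp[1])),
        sum(apply(w, 2, sum) * seq_len(shp[2])),
        sum(apply(w, 3, sum) * seq_len(shp[3]))) / tot
    } else (shp + 1) / 2
  }
  lo <- round(center - crop_shape / 2)
  lo <- pmin(pmax(lo, 1L), pmax(shp - crop_shape + 1L, 1L))
  hi <- pmin(lo + crop_shape - 1L, shp)
  cr <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (any(dim(cr) < crop_shape)) {  # symmetric zero padding on short axes
    pad <- array(0, dim = crop_shape)
    off <- (crop_shape - dim(cr)) %/% 2L
    pad[off[1] + seq_len(dim(cr)[1]), off[2] + seq_len(dim(cr)[2]),
        off[3] + seq_len(dim(cr)[3])] <- cr
    cr <- pad
    lo <- lo - off
  }
  nxo <- crop_shape[1] %/% down
  nyo <- crop_shape[2] %/% down
  out <- array(cpp_resize_bicubic_xy(as.numeric(cr), dim(cr), nxo, nyo),
               dim = c(nxo, nyo, crop_shape[3]))
  g <- if (inherits(vol, "recon_volume")) vol$grid else NULL
  newgrid <- if (!is.null(g)) {
    grid_spec(c(nxo, nyo, crop_shape[3]),
              pitch = c(g$pitch[1] * down, g$pitch[2] * down, g$pitch[3]),
              origin = g$origin + (lo - 1L) * g$pitch)
  } else grid_spec(c(nxo, nyo, crop_shape[3]), 1)
  res <- recon_volume(out, newgrid,
                      if (inherits(vol, "recon_volume")) vol$provenance
                      else list(kind = "unknown", elements = NA))
  attr(res, "roi_center") <- center
  res
}

#' Pair and normalize a sparse/dense reconstruction
#'
#' Both members are mapped with the affine transform that takes the dense
#' (ground-truth) volume's value range to [0, 1]; the sparse member shares
#' the dense scale factor, so it may slightly exceed [0, 1].
#'
#' @param sparse,dense `recon_volume`s on identical grids.
#' @return an object of class `paired_volume` with normalized `sparse`,
#'   `dense` members and the `scale` used.
#' @export
normalize_pair <- function(sparse, dense) {
  sv <- as_values(sparse); dv <- as_values(dense)
  if (!all(dim(sv) == dim(dv))) stopf("paired volumes must share a shape")
  r <- range(dv)
  sc <- if (diff(r) > 0) diff(r) else 1
  dn <- (dv - r[1]) / sc
  sn <- (sv - r[1]) / sc
  structure(list(sparse = sn, dense = dn, scale = list(min = r[1], range = sc),
                 grid = if (inherits(dense, "recon_volume")) dense$grid else NULL),
            class = "paired_volume")
}

#' Draw one paired random training patch
#'
#' Draws a patch corner uniformly, extracts the same window from the sparse
#' and dense members, and applies the same random flips along the two
#' coronal in-plane axes (each with probability `flip_prob`). Deterministic
#' given the seed.
#'
#' @param pair a `paired_volume`.
#' @param seed integer seed.
#' @param patch cubic patch side in voxels.
#' @param flip_prob per-axis flip probability.
#' @return list with `sparse`, `dense` (patch arrays), `corner` (0-based)
#'   and `flips` (logical length 2).
#' @export
random_training_patch <- function(pair, seed, patch = 96L, flip_prob = 0.5) {
  d <- dim(pair$dense)
  patch <- as.integer(patch)
  if (any(d < patch)) stopf("volume dims (%s) below the patch size %d",
                            paste(d, collapse = "x"), patch)
  with_seed(seed, {
    corner <- vapply(d, function(n) sample.int(n - patch + 1L, 1L) - 1L, integer(1))
    flips <- stats::runif(2) < flip_prob
    ix <- (corner[1] + 1L):(corner[1] + patch)
    iy <- (corner[2] + 1L):(corner[2] + patch)
    iz <- (corner[3] + 1L):(corner[3] + patch)
    if (flips[1]) ix <- rev(ix)
    if (flips[2]) iy <- rev(iy)
    list(sparse = pair$sparse[ix, iy, iz], dense = pair$dense[ix, iy, iz],
         corner = corner, flips = flips)
  })
}

#' Tile a volume into overlapping cubic patches
#'
#' Equal-stride patch corners per axis with the last patch flush to the
#' boundary, guaranteeing full coverage.
#'
#' @param vol a `recon_volume` or 3D array.
#' @param patch patch side in voxels.
#' @param overlap minimum overlap between neighboring patches (voxels);
#'   must satisfy 0 <= overlap < patch.
#' @param sigma Gaussian stitching weight sigma (voxels); default patch/4.
#' @return an object of class `patch_set`: `patches` (list of arrays),
#'   `corners` (n x 3, 0-based), `shape`, `patch`, `sigma`.
#' @export
tile_volume <- function(vol, patch = 96L, overlap = NULL, sigma = NULL) {
  v <- as_values(vol)
  d <- dim(v)
  patch <- as.integer(patch)
  overlap <- as.integer(overlap %||% max(1L, patch %/% 3L))
  if (any(d < patch)) stopf("volume dims (%s) below the patch size %d",
                            paste(d, collapse = "x"), patch)
  if (overlap < 0L || overlap >= patch) stopf("overlap must satisfy 0 <= overlap < patch")
  stride <- patch - overlap
  corners_axis <- function(n) {
    if (n == patch) return(0L)
    k <- ceiling((n - patch) / stride) + 1L
    as.integer(round(seq(0L, n - patch, length.out = k)))
  }
  cx <- corners_axis(d[1]); cy <- corners_axis(d[2]); cz <- corners_axis(d[3])
  corners <- as.matrix(expand.grid(cx, cy, cz))
  colnames(corners) <- NULL
  patches <- lapply(seq_len(nrow(corners)), function(i) {
    co <- corners[i, ]
    v[(co[1] + 1L):(co[1] + patch), (co[2] + 1L):(co[2] + patch),
      (co[3] + 1L):(co[3] + patch)]
  })
  structure(list(patches = patches, corners = corners, shape = d, patch = patch,
                 sigma = sigma %||% (patch / 4)),
            class = "patch_set")
}

#' Stitch patches with Gaussian weighting
#'
#' Reassembles a volume as the per-voxel weighted average of all covering
#' patches, with a separable Gaussian window centered in each patch. The
#' window is strictly positive, so stitching an unmodified tiling returns
#' the original volume (up to float rounding).
#'
#' @param ps a `patch_set`.
#' @return 3D array of the stitched volume.
#' @export
stitch_gaussian <- function(ps) {
  p <- ps$patch
  w1 <- stats::dnorm(((0:(p - 1)) - (p - 1) / 2) / ps$sigma)
  W <- outer(outer(w1, w1), w1)
  num <- array(0, dim = ps$shape)
  den <- array(0, dim = ps$shape)
  for (i in seq_along(ps$patches)) {
    co <- ps$corners[i, ]
    ix <- (co[1] + 1L):(co[1] + p); iy <- (co[2] + 1L):(co[2] + p); iz <- (co[3] + 1L):(co[3] + p)
    num[ix, iy, iz] <- num[ix, iy, iz] + W * ps$patches[[i]]
    den[ix, iy, iz] <- den[ix, iy, iz] + W
  }
  if (any(den == 0)) stopf("patch set does not cover the volume")
  num / den
}
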