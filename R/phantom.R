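#' Voxel grid specification
#'
#' Describes a regular 3D voxel grid: the number of voxels per axis, the
#' voxel pitch, and the physical coordinate of the first voxel center.
#' The coronal plane is x-y; +z points from the chest wall toward the
#' nipple (the illuminated face).
#'
#' @param shape integer vector of length 3, voxels along x, y, z.
#' @param pitch voxel pitch in mm; a scalar for cubic voxels or a length-3
#'   vector for anisotropic grids (produced e.g. by in-plane downsampling).
#' @param origin physical coordinate (mm) of the center of voxel (0,0,0).
#'   Defaults to `pitch/2` so that voxel i spans `[i*pitch, (i+1)*pitch)`.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(shape, pitch, origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stopf("shape must be 3 positive integers")
  if (!length(pitch) %in% c(1L, 3L) || any(pitch <= 0)) stopf("pitch must be positive")
  pitch <- rep(as.numeric(pitch), length.out = 3L)
  origin <- origin %||% (pitch / 2)
  structure(list(shape = shape, pitch = pitch, origin = as.numeric(origin)),
            class = "grid_spec")
}

#' Default simulation grid
#'
#' 359 x 287 x 153 voxels at 0.25 mm pitch.
#' @return a [grid_spec()].
#' @export
default_grid <- function() grid_spec(c(359L, 287L, 153L), 0.25)

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid: %d x %d x %d voxels @ (%s) mm\n", x$shape[1], x$shape[2],
              x$shape[3], paste(signif(x$pitch, 4), collapse = ", ")))
  invisible(x)
}

grid_extent <- function(grid) grid$shape * grid$pitch

# physical (mm) centers of voxels along one axis, 0-based indexing
axis_centers <- function(grid, a) grid$origin[a] + (seq_len(grid$shape[a]) - 1L) * grid$pitch[a]

#' Tissue label codes
#'
#' The seven tissue classes of the digital breast phantom, as integer label
#' codes used in [generate_phantom()] volumes.
#' @return named integer vector.
#' @export
tissue_labels <- function() {
  c(AIR = 0L, FAT = 1L, SKIN = 2L, GLAND = 3L, MUSCLE = 4L, FIBER = 5L, VEIN = 6L)
}

#' Phantom generation parameters
#'
#' Geometric and compositional parameters of the procedural breast phantom:
#' a half-ellipsoid breast in prone orientation resting on a muscle slab at
#' the chest-wall face, a closed skin shell, a fat/gland partition from
#' thresholded smoothed noise calibrated to a target gland volume fraction,
#' a recursive branching vessel tree with tapering diameters, and thin
#' fiber strands.
#'
#' @param semi_axes breast semi-axes (mm) along x, y, z.
#' @param skin_thickness skin shell thickness (mm).
#' @param gland_fraction target GLAND/(GLAND+FAT) volume fraction; the
#'   default 0.339 corresponds to a heterogeneously dense breast.
#' @param vessel_depth branching depth of the vessel tree (0 = no vessels).
#' @param vessel_root_diameter diameter (mm) of the tree root.
#' @param vessel_taper per-generation diameter taper factor.
#' @param n_fibers number of thin fiber strands.
#' @param fiber_radius fiber strand radius (mm).
#' @param muscle_thickness chest-wall muscle slab thickness (mm).
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(semi_axes = c(36, 30, 32), skin_thickness = 1.5,
                           gland_fraction = 0.339, vessel_depth = 5L,
                           vessel_root_diameter = 2.5, vessel_taper = 0.78,
                           n_fibers = 30L, fiber_radius = 0.3,
                           muscle_thickness = 3) {
  if (any(semi_axes <= 0) || skin_thickness <= 0 || muscle_thickness <= 0)
    stopf("all lengths must be positive")
  if (gland_fraction < 0 || gland_fraction > 1) stopf("gland_fraction must be in [0,1]")
  structure(list(semi_axes = as.numeric(semi_axes), skin_thickness = skin_thickness,
                 gland_fraction = gland_fraction, vessel_depth = as.integer(vessel_depth),
                 vessel_root_diameter = vessel_root_diameter, vessel_taper = vessel_taper,
                 n_fibers = as.integer(n_fibers), fiber_radius = fiber_radius,
                 muscle_thickness = muscle_thickness),
            class = "phantom_params")
}

# trilinear interpolation of a coarse noise field at arbitrary voxel coords
smooth_noise_field <- function(grid, stride_vox = 8L, pts) {
  cs <- pmax(2L, ceiling(grid$shape / stride_vox) + 1L)
  G <- array(stats::rnorm(prod(cs)), dim = cs)
  f <- (pts - 1) / stride_vox + 1  # coarse-grid coordinates, 1-based
  f <- pmin(pmax(f, 1), matrix(rep(cs - 1e-9, each = nrow(pts)), ncol = 3))
  i0 <- pmin(floor(f), matrix(rep(cs - 1L, each = nrow(pts)), ncol = 3))
  w <- f - i0
  v <- numeric(nrow(pts))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ww <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    v <- v + ww * G[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  v
}

# Stamp spheres of given radii (mm) centered at points (mm) into a logical
# array. Marks at least the nearest voxel per point so thin strands stay
# 26-connected.
stamp_spheres <- function(mask, grid, pts, radii) {
  shp <- grid$shape; p <- grid$pitch
  for (i in seq_len(nrow(pts))) {
    ctr <- (pts[i, ] - grid$origin) / p  # 0-based voxel coordinate of center
    r <- radii[i] / p
    i0 <- pmax(0L, floor(ctr - r)); i1 <- pmin(shp - 1L, ceiling(ctr + r))
    if (any(i0 > i1)) next
    xs <- i0[1]:i1[1]; ys <- i0[2]:i1[2]; zs <- i0[3]:i1[3]
    dx2 <- ((xs - ctr[1]) / r[1])^2
    dy2 <- ((ys - ctr[2]) / r[2])^2
    dz2 <- ((zs - ctr[3]) / r[3])^2
    sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    mask[xs + 1L, ys + 1L, zs + 1L] <-
      mask[xs + 1L, ys + 1L, zs + 1L, drop = FALSE] | sub
    nn <- pmin(pmax(round(ctr), 0L), shp - 1L)
    mask[nn[1] + 1L, nn[2] + 1L, nn[3] + 1L] <- TRUE
  }
  mask
}

# Recursive branching vessel tree. Returns a matrix of sampled centerline
# points (mm) with per-point radii, guaranteed continuous along segments.
grow_vessel_tree <- function(params, center, z0, grid) {
  ax <- params$semi_axes
  inside <- function(p, frac = 0.88) {
    e <- ((p[1] - center[1]) / (ax[1] - params$skin_thickness))^2 +
         ((p[2] - center[2]) / (ax[2] - params$skin_thickness))^2 +
         ((p[3] - z0) / (ax[3] - params$skin_thickness))^2
    e <= frac && p[3] >= z0
  }
  pts <- NULL; rad <- NULL
  step <- min(grid$pitch) * 0.5
  recurse <- function(start, dir, len, r, depth) {
    if (depth <= 0L) return(invisible())
    end <- start + len * dir
    tries <- 0L
    while (!inside(end) && tries < 25L) { len <- len * 0.75; end <- start + len * dir; tries <- tries + 1L }
    if (!inside(end)) return(invisible())
    n <- max(2L, ceiling(len / step))
    tt <- seq(0, 1, length.out = n)
    seg <- cbind(start[1] + tt * (end[1] - start[1]),
                 start[2] + tt * (end[2] - start[2]),
                 start[3] + tt * (end[3] - start[3]))
    pts <<- rbind(pts, seg); rad <<- c(rad, rep(r, n))
    for (k in 1:2) {
      # child direction: tilt the parent direction by a random angle
      ang <- stats::runif(1, 20, 55) * pi / 180
      phi <- stats::runif(1, 0, 2 * pi)
      # orthonormal frame around dir
      up <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- cross3(dir, up); e1 <- e1 / sqrt(sum(e1^2))
      e2 <- cross3(dir, e1)
      nd <- cos(ang) * dir + sin(ang) * (cos(phi) * e1 + sin(phi) * e2)
      nd <- nd / sqrt(sum(nd^2))
      recurse(end, nd, len * stats::runif(1, 0.65, 0.85), r * params$vessel_taper, depth - 1L)
    }
  }
  root_dir <- c(0, 0, 1)
  recurse(c(center[1], center[2], z0 + min(grid$pitch)), root_dir,
          0.45 * ax[3], params$vessel_root_diameter / 2, params$vessel_depth)
  list(pts = pts, rad = rad)
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Generate a synthetic digital breast phantom
#'
#' Builds a labeled 3D tissue volume with the seven classes AIR, FAT, SKIN,
#' GLAND, MUSCLE, FIBER and VEIN: a prone half-ellipsoid breast with a
#' closed skin shell on a chest-wall muscle slab, a gland compartment from
#' smoothed noise thresholded to the target gland volume fraction, a
#' connected branching vessel tree with tapering diameters, and thin fiber
#' strands. Deterministic given (seed, grid, params).
#'
#' @param seed integer seed controlling all randomness.
#' @param grid a [grid_spec()]; defaults to [default_grid()].
#' @param params a [phantom_params()].
#' @return an object of class `tissue_volume` with fields `labels`
#'   (3D integer array), `grid`, `seed` and `params`.
#' @export
generate_phantom <- function(seed, grid = default_grid(), params = phantom_params()) {
  lb <- tissue_labels()
  ext <- grid_extent(grid)
  ax <- params$semi_axes
  z0 <- params$muscle_thickness
  ctr <- c(ext[1] / 2, ext[2] / 2)
  margin <- grid$pitch
  if (ax[1] + margin[1] > ext[1] / 2) stopf("breast exceeds the grid along x")
  if (ax[2] + margin[2] > ext[2] / 2) stopf("breast exceeds the grid along y")
  if (z0 + ax[3] + margin[3] > ext[3]) stopf("breast exceeds the grid along z")

  with_seed(seed, {
    xs <- axis_centers(grid, 1); ys <- axis_centers(grid, 2); zs <- axis_centers(grid, 3)
    labels <- array(lb[["AIR"]], dim = grid$shape)
    labels[, , zs < z0] <- lb[["MUSCLE"]]

    exq <- ((xs - ctr[1]) / ax[1])^2
    eyq <- ((ys - ctr[2]) / ax[2])^2
    ezq <- ((zs - z0) / ax[3])^2
    E <- outer(outer(exq, eyq, "+"), ezq, "+")
    zup <- rep(rep(zs >= z0, each = grid$shape[1] * grid$shape[2]), 1)
    breast <- (E <= 1) & array(zup, dim = grid$shape)
    axi <- ax - params$skin_thickness
    E2 <- outer(outer(((xs - ctr[1]) / axi[1])^2, ((ys - ctr[2]) / axi[2])^2, "+"),
                ((zs - z0) / axi[3])^2, "+")
    interior <- (E2 <= 1) & breast
    labels[breast] <- lb[["SKIN"]]
    labels[interior] <- lb[["FAT"]]

    # gland compartment: smoothed noise thresholded to the target fraction
    ii <- which(interior)
    if (length(ii)) {
      pv <- arrayInd(ii, grid$shape)
      field <- smooth_noise_field(grid, 8L, pv)
      if (params$gland_fraction > 0) {
        th <- stats::quantile(field, 1 - params$gland_fraction, names = FALSE)
        labels[ii[field > th]] <- lb[["GLAND"]]
      }
    }

    # fiber strands
    if (params$n_fibers > 0L && length(ii)) {
      fmask <- array(FALSE, dim = grid$shape)
      for (k in seq_len(params$n_fibers)) {
        for (try in 1:50) {
          s <- c(stats::runif(1, ctr[1] - axi[1], ctr[1] + axi[1]),
                 stats::runif(1, ctr[2] - axi[2], ctr[2] + axi[2]),
                 stats::runif(1, z0, z0 + axi[3]))
          e2 <- ((s[1] - ctr[1]) / axi[1])^2 + ((s[2] - ctr[2]) / axi[2])^2 + ((s[3] - z0) / axi[3])^2
          if (e2 <= 0.8) break
        }
        d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
        len <- stats::runif(1, 8, 15)
        n <- max(2L, ceiling(len / (min(grid$pitch) * 0.5)))
        tt <- seq(0, 1, length.out = n)
        seg <- cbind(s[1] + tt * len * d[1], s[2] + tt * len * d[2], s[3] + tt * len * d[3])
        fmask <- stamp_spheres(fmask, grid, seg, rep(params$fiber_radius, n))
      }
      sel <- fmask & interior & (labels == lb[["FAT"]] | labels == lb[["GLAND"]])
      labels[sel] <- lb[["FIBER"]]
    }

    # vessel tree (rasterized last so veins are never overwritten)
    if (params$vessel_depth > 0L) {
      tree <- grow_vessel_tree(params, ctr, z0, grid)
      if (!is.null(tree$pts)) {
        vmask <- array(FALSE, dim = grid$shape)
        vmask <- stamp_spheres(vmask, grid, tree$pts, tree$rad)
        sel <- vmask & interior
        labels[sel] <- lb[["VEIN"]]
      }
    }

    structure(list(grid = grid, labels = labels, seed = as.integer(seed),
                   params = params), class = "tissue_volume")
  })
}

#' @export
print.tissue_volume <- function(x, ...) {
  cat("tissue_volume (digital breast phantom)\n")
  print(x$grid)
  tab <- table(factor(x$labels, levels = tissue_labels(),
                      labels = names(tissue_labels())))
  print(tab)
  invisible(x)
}

#' Optical property table at 757 nm
#'
#' Absorption coefficient (1/cm), scattering coefficient (1/cm) and
#' Henyey-Greenstein anisotropy for the seven tissue classes.
#'
#' @return data.frame with columns `tissue`, `label`, `mu_a`, `mu_s`, `g`.
#' @export
optical_properties_table <- function() {
  lb <- tissue_labels()
  data.frame(
    tissue = names(lb),
    label = unname(lb),
    mu_a = c(1e-12, 0.62, 0.48, 0.36, 0.52, 0.13, 4),
    mu_s = c(1e-12, 73, 167, 112, 73.6, 115, 71.4),
    g = c(1, 0.98, 0.9, 0.96, 0.93, 0.13, 0.9)
  )
}

#' Attach optical properties to a tissue volume
#'
#' Per-voxel lookup of absorption, scattering and anisotropy from a label
#' table; the output grids share the phantom's [grid_spec()].
#'
#' @param vol a `tissue_volume`.
#' @param table a data.frame like [optical_properties_table()] covering
#'   every label present in `vol`.
#' @return list with 3D arrays `mu_a`, `mu_s` (1/cm), `g`, and `grid`.
#' @export
assign_optical_properties <- function(vol, table = optical_properties_table()) {
  present <- sort(unique(as.vector(vol$labels)))
  missing <- setdiff(present, table$label)
  if (length(missing)) {
    lb <- tissue_labels()
    nm <- names(lb)[match(missing, lb)]
    stopf("optical property table is missing labels: %s",
          paste(ifelse(is.na(nm), missing, nm), collapse = ", "))
  }
  m <- match(as.vector(vol$labels), table$label)
  shp <- vol$grid$shape
  list(mu_a = array(table$mu_a[m], dim = shp),
       mu_s = array(table$mu_s[m], dim = shp),
       g = array(table$g[m], dim = shp),
       grid = vol$grid)
}

#' Binary vessel mask
#'
#' @param vol a `tissue_volume`.
#' @return logical 3D array, `TRUE` exactly where the label is VEIN.
#' @export
vessel_mask <- function(vol) vol$labels == tissue_labels()[["VEIN"]]
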