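test_that("phantom generation is deterministic and partitions every voxel", {
  g <- small_grid()
  v1 <- generate_phantom(7L, g, small_params())
  v2 <- generate_phantom(7L, g, small_params())
  expect_identical(v1$labels, v2$labels)

  lb <- tissue_labels()
  counts <- table(factor(v1$labels, levels = lb))
  expect_equal(sum(counts), prod(g$shape))
  expect_true(all(as.vector(v1$labels) %in% lb))

  v3 <- generate_phantom(8L, g, small_params())
  expect_false(identical(v1$labels, v3$labels))
})

test_that("default-grid phantom contains all seven tissue classes", {
  vol <- generate_phantom(1L)
  expect_identical(dim(vol$labels), c(359L, 287L, 153L))
  expect_setequal(unique(as.vector(vol$labels)), unname(tissue_labels()))
  # AIR everywhere on the illuminated (+z) face
  expect_true(all(vol$labels[, , dim(vol$labels)[3]] == tissue_labels()[["AIR"]]))
})

test_that("vessel branching depth 0 yields no vein voxels", {
  vol <- generate_phantom(3L, small_grid(), small_params(vessel_depth = 0L))
  expect_equal(sum(vol$labels == tissue_labels()[["VEIN"]]), 0)
  expect_false(any(vessel_mask(vol)))
})

test_that("realized gland fraction is close to the target", {
  lb <- tissue_labels()
  for (seed in c(2L, 9L)) {
    vol <- generate_phantom(seed, small_grid(), small_params())
    ng <- sum(vol$labels == lb[["GLAND"]])
    nf <- sum(vol$labels == lb[["FAT"]])
    expect_lt(abs(ng / (ng + nf) - 0.339), 0.1)
  }
})

test_that("vessel mask matches labels and the tree is 26-connected", {
  vol <- generate_phantom(4L, small_grid(), small_params())
  m <- vessel_mask(vol)
  expect_equal(sum(m), sum(vol$labels == tissue_labels()[["VEIN"]]))
  expect_gt(sum(m), 0)

  # flood fill by repeated 26-neighborhood dilation from the lowest vein voxel
  idx <- which(m, arr.ind = TRUE)
  seedvox <- idx[which.min(idx[, 3]), ]
  reach <- array(FALSE, dim = dim(m))
  reach[seedvox[1], seedvox[2], seedvox[3]] <- TRUE
  dims <- dim(m)
  repeat {
    grown <- reach
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xs <- pmin(pmax(1:dims[1] + dx, 1), dims[1])
      ys <- pmin(pmax(1:dims[2] + dy, 1), dims[2])
      zs <- pmin(pmax(1:dims[3] + dz, 1), dims[3])
      grown <- grown | reach[xs, ys, zs]
    }
    grown <- grown & m
    if (identical(grown, reach)) break
    reach <- grown
  }
  expect_true(all(reach[m]))
})

test_that("oversized breast fails naming the overfull axis", {
  g <- small_grid()
  expect_error(generate_phantom(1L, g, small_params(semi_axes = c(60, 13, 14))),
               "along x")
  expect_error(generate_phantom(1L, g, small_params(semi_axes = c(14, 13, 40))),
               "along z")
})

test_that("optical property lookup matches the 757 nm table", {
  vol <- generate_phantom(2L, small_grid(), small_params())
  pr <- assign_optical_properties(vol)
  lb <- tissue_labels()
  vein <- vol$labels == lb[["VEIN"]]
  expect_true(all(pr$mu_a[vein] == 4))
  expect_true(all(pr$mu_s[vein] == 71.4))
  expect_true(all(pr$g[vein] == 0.9))
  air <- vol$labels == lb[["AIR"]]
  expect_true(all(pr$mu_a[air] == 1e-12))
  expect_identical(dim(pr$mu_a), vol$grid$shape)

  tab <- optical_properties_table()
  expect_error(assign_optical_properties(vol, tab[tab$tissue != "FIBER", ]),
               "FIBER")
})

test_that("phantom round-trips through NIfTI with its parameters", {
  vol <- generate_phantom(5L, small_grid(), small_params())
  path <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(c(path, paste0(path, ".yaml"))), add = TRUE)
  write_phantom(vol, path)
  back <- read_phantom(path)
  expect_identical(back$labels, vol$labels)
  expect_equal(back$grid$pitch, vol$grid$pitch)
  expect_equal(back$params$gland_fraction, vol$params$gland_fraction)
})
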