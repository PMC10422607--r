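#' Training configuration
#'
#' Optimization protocol for the Res-UNet: Adam with the stated learning
#' rate and weight decay, batched random paired patches with in-plane
#' flips, composite L1/MS-SSIM loss, and early stopping on the validation
#' loss.
#'
#' @param lr Adam learning rate.
#' @param weight_decay L2 weight decay added to gradients.
#' @param batch_size patches per optimization step.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param min_delta minimum validation-loss improvement that resets
#'   patience.
#' @param patch training patch side (voxels); must be divisible by
#'   2^levels of the model.
#' @param patches_per_volume random crops drawn per training volume per
#'   epoch (random cropping expands the effective training set).
#' @param val_patches_per_volume fixed seeded patches per validation volume
#'   used for the early-stopping loss.
#' @param flip_prob per-axis probability of coronal in-plane flips.
#' @param weights a [loss_weights()].
#' @param seed integer seed driving patch sampling and shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 0.0025, weight_decay = 0.001, batch_size = 3L,
                         max_epochs = 300L, patience = 20L, min_delta = 1e-4,
                         patch = 96L, patches_per_volume = 2L,
                         val_patches_per_volume = 4L, flip_prob = 0.5,
                         weights = loss_weights(), seed = 1L) {
  if (lr <= 0 || batch_size < 1L || max_epochs < 0L) stopf("invalid train_config")
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 min_delta = min_delta, patch = as.integer(patch),
                 patches_per_volume = as.integer(patches_per_volume),
                 val_patches_per_volume = as.integer(val_patches_per_volume),
                 flip_prob = flip_prob, weights = weights, seed = as.integer(seed)),
            class = "train_config")
}

stack_batch <- function(patches) {
  matrix(unlist(lapply(patches, as.numeric), use.names = FALSE), ncol = 1)
}

eval_loss_pairs <- function(model, patches, w) {
  tot <- 0
  for (pp in patches) {
    r <- resunet_forward(model, matrix(as.numeric(pp$sparse), ncol = 1),
                         dim(pp$sparse), B = 1L, training = FALSE)
    tot <- tot + composite_loss(array(r$out, dim = dim(pp$dense)), pp$dense, w)
  }
  tot / length(patches)
}

#' Train a Res-UNet on paired sparse/dense volumes
#'
#' Each epoch draws `patches_per_volume` random paired patches per training
#' volume (seeded), shuffles them into batches, and takes Adam steps on the
#' composite loss. The validation loss is evaluated each epoch on a fixed
#' seeded patch set;
#' training stops early after `patience` epochs without improvement, and
#' the best-validation weights are returned. A non-finite training loss
#' aborts with the last finite weights.
#'
#' @param train_pairs,val_pairs lists of `paired_volume`s.
#' @param model a [res_unet()] (initialized, or initialized here from the
#'   config seed).
#' @param config a [train_config()].
#' @return object of class `resunet_fit`: `model` (best weights),
#'   `history` (data.frame epoch/train_loss/val_loss), `config`,
#'   `best_epoch`, `diverged`.
#' @export
train_resunet <- function(train_pairs, val_pairs, model, config = train_config()) {
  if (!length(train_pairs)) stopf("empty training split")
  if (is.null(model$params)) model <- init_he_normal(model, config$seed)
  w <- config$weights
  if (config$max_epochs == 0L) {
    return(structure(list(model = model, history = data.frame(
      epoch = integer(), train_loss = numeric(), val_loss = numeric()),
      config = config, best_epoch = NA_integer_, diverged = FALSE),
      class = "resunet_fit"))
  }
  if (!length(val_pairs)) stopf("empty validation split")
  p <- config$patch
  # fixed, seeded validation patches (flips off) for a stable stopping signal
  val_patches <- unlist(lapply(seq_along(val_pairs), function(i) {
    lapply(seq_len(config$val_patches_per_volume), function(j) {
      random_training_patch(val_pairs[[i]],
                            seed = seed_stream(config$seed, 900000L + i * 100L + j),
                            patch = p, flip_prob = 0)
    })
  }), recursive = FALSE)
  flat <- flatten_params(model$params, trainable_only = TRUE)
  state <- adam_init(flat)
  best <- model$params
  best_val <- Inf
  best_epoch <- NA_integer_
  bad <- 0L
  diverged <- FALSE
  hist <- vector("list", config$max_epochs)
  n <- length(train_pairs) * config$patches_per_volume
  for (ep in seq_len(config$max_epochs)) {
    ord <- with_seed(seed_stream(config$seed, ep),
                     sample(rep(seq_along(train_pairs), config$patches_per_volume)))
    patches <- lapply(seq_len(n), function(i) {
      random_training_patch(train_pairs[[ord[i]]],
                            seed = seed_stream(config$seed, ep * 10007L + i),
                            patch = p, flip_prob = config$flip_prob)
    })
    ep_loss <- 0; nb <- 0L
    prev_params <- model$params
    for (b0 in seq(1L, n, by = config$batch_size)) {
      bidx <- b0:min(b0 + config$batch_size - 1L, n)
      xs <- stack_batch(lapply(patches[bidx], `[[`, "sparse"))
      ts <- lapply(patches[bidx], `[[`, "dense")
      B <- length(bidx)
      fw <- resunet_forward(model, xs, rep(p, 3L), B = B, training = TRUE)
      model <- fw$model
      nv <- p^3
      douts <- matrix(0, B * nv, 1L)
      bl <- 0
      for (i in seq_len(B)) {
        rows <- (i - 1L) * nv + seq_len(nv)
        lg <- composite_loss_grad(array(fw$out[rows, 1L], dim = dim(ts[[i]])), ts[[i]], w)
        bl <- bl + lg$loss / B
        douts[rows, 1L] <- as.numeric(lg$grad) / B
      }
      if (!is.finite(bl)) { diverged <- TRUE; model$params <- prev_params; break }
      grads <- resunet_backward(model, fw$cache, douts)
      gflat <- flatten_params(grads, trainable_only = TRUE)
      upd <- adam_step(flatten_params(model$params, trainable_only = TRUE),
                       gflat, state, config$lr, config$weight_decay)
      state <- upd$state
      model$params <- assign_flat(model$params, upd$flat)
      ep_loss <- ep_loss + bl; nb <- nb + 1L
    }
    if (diverged) {
      warning("non-finite training loss; stopping with last finite weights")
      break
    }
    train_loss <- ep_loss / nb
    val_loss <- eval_loss_pairs(model, val_patches, w)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = train_loss, val_loss = val_loss)
    if (is.finite(val_loss) && val_loss < best_val - config$min_delta) {
      best_val <- val_loss; best <- model$params; best_epoch <- ep; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$patience) break
    }
  }
  model$params <- best
  structure(list(model = model, history = do.call(rbind, hist), config = config,
                 best_epoch = best_epoch, diverged = diverged),
            class = "resunet_fit")
}

#' @export
print.resunet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("resunet_fit: %d epochs (best %s), final train loss %s, best val loss %s\n",
              NROW(h), as.character(x$best_epoch),
              if (NROW(h)) signif(h$train_loss[NROW(h)], 4) else "NA",
              if (!is.na(x$best_epoch)) signif(min(h$val_loss, na.rm = TRUE), 4) else "NA"))
  invisible(x)
}

#' @export
predict.resunet_fit <- function(object, newdata, ...) predict(object$model, newdata, ...)

#' Patch-wise network inference on a full volume
#'
#' Tiles the volume into overlapping patches, runs each through the
#' network in evaluation mode, and re-assembles the outputs with
#' Gaussian-weighted stitching. Deterministic given a fixed checkpoint.
#'
#' @param fit a `resunet_fit` or initialized `res_unet`.
#' @param vol `recon_volume` or 3D array with every side >= patch.
#' @param patch patch side (divisible by 2^levels).
#' @param overlap tiling overlap in voxels (default patch/3).
#' @return a `recon_volume` with provenance kind "dnn" (3D array in, array
#'   grid out on a unit grid).
#' @export
infer_volume <- function(fit, vol, patch = 96L, overlap = NULL) {
  model <- if (inherits(fit, "resunet_fit")) fit$model else fit
  v <- as_values(vol)
  if (any(dim(v) < patch)) stopf("volume dims (%s) below the patch size %d",
                                 paste(dim(v), collapse = "x"), patch)
  ps <- tile_volume(v, patch = patch, overlap = overlap)
  for (i in seq_along(ps$patches)) {
    r <- resunet_forward(model, matrix(as.numeric(ps$patches[[i]]), ncol = 1),
                         rep(ps$patch, 3L), B = 1L, training = FALSE)
    ps$patches[[i]] <- array(r$out, dim = rep(ps$patch, 3L))
  }
  out <- stitch_gaussian(ps)
  g <- if (inherits(vol, "recon_volume")) vol$grid else grid_spec(dim(v), 1)
  el <- if (inherits(vol, "recon_volume")) vol$provenance$elements else NA
  recon_volume(out, g, list(kind = "dnn", elements = el))
}

#' Dataset simulation specification
#'
#' Defines the study conditions for a simulated paired dataset: the
#' phantom grid and parameters, Monte-Carlo photon budget, hemispherical
#' array, detection band, reconstruction grid, ROI crop, and the sparse
#' element counts.
#'
#' @param n_phantoms number of phantoms (>= 3 so every split is
#'   non-empty).
#' @param element_counts sparse element counts to reconstruct.
#' @param dense_elements elements of the fully sampled array (ground
#'   truth).
#' @param master_seed seed from which all per-phantom seeds derive.
#' @param grid phantom [grid_spec()].
#' @param params [phantom_params()].
#' @param n_photons Monte-Carlo photon packets per phantom.
#' @param beam a [beam_spec()].
#' @param array_radius hemisphere radius (m).
#' @param fs sampling rate (Hz).
#' @param f0,fractional_bw transducer band.
#' @param lowpass_cutoff signal-conditioning low-pass cutoff (Hz).
#' @param recon_grid reconstruction [grid_spec()]; `NULL` reconstructs on
#'   the phantom grid.
#' @param crop_shape ROI crop (voxels) applied before in-plane
#'   downsampling.
#' @return object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_phantoms = 140L,
                         element_counts = c(256L, 310L, 360L, 410L, 460L, 512L),
                         dense_elements = 5120L, master_seed = 1L,
                         grid = default_grid(), params = phantom_params(),
                         n_photons = 1e6, beam = beam_spec(),
                         array_radius = 0.048, fs = 20e6, f0 = 2.5e6,
                         fractional_bw = 0.7, lowpass_cutoff = 4e6,
                         recon_grid = NULL, crop_shape = c(310L, 310L, 128L)) {
  if (n_phantoms < 3L) stopf("n_phantoms must be >= 3 so every split is non-empty")
  structure(list(n_phantoms = as.integer(n_phantoms),
                 element_counts = as.integer(element_counts),
                 dense_elements = as.integer(dense_elements),
                 master_seed = as.integer(master_seed), grid = grid,
                 params = params, n_photons = n_photons, beam = beam,
                 array_radius = array_radius, fs = fs, f0 = f0,
                 fractional_bw = fractional_bw, lowpass_cutoff = lowpass_cutoff,
                 recon_grid = recon_grid, crop_shape = as.integer(crop_shape)),
            class = "dataset_spec")
}

#' Desk-scale dataset specification
#'
#' A reduced configuration for workstation-scale runs: 128 x 128 x 64
#' phantoms at 0.5 mm pitch, a 1024-element dense hemisphere, 2e5 photon
#' packets, reconstruction on a breast-centered 96 x 96 x 64 grid, and an
#' ROI pipeline yielding 48 x 48 x 64 paired volumes.
#'
#' @param master_seed master seed.
#' @param n_phantoms number of phantoms.
#' @param element_counts sparse counts.
#' @return a [dataset_spec()].
#' @export
desk_dataset_spec <- function(master_seed, n_phantoms = 20L,
                              element_counts = c(64L, 128L, 256L)) {
  grid <- grid_spec(c(128L, 128L, 64L), 0.5)
  params <- phantom_params(semi_axes = c(22, 20, 22), skin_thickness = 1.5,
                           vessel_depth = 5L, vessel_root_diameter = 2.5,
                           n_fibers = 12L, muscle_thickness = 2)
  ext <- grid_extent(grid)
  rg <- grid_spec(c(96L, 96L, 64L), 0.5,
                  origin = c(ext[1] / 2 - 24 + 0.25, ext[2] / 2 - 24 + 0.25, 0.25))
  dataset_spec(n_phantoms = n_phantoms, element_counts = element_counts,
               dense_elements = 1024L, master_seed = master_seed, grid = grid,
               params = params, n_photons = 2e5, recon_grid = rg,
               crop_shape = c(96L, 96L, 64L))
}

# deterministic 0.8/0.1/0.1 split: shuffle by the master seed, then
# floor(0.8 n) / floor(0.1 n) / remainder
split_dataset <- function(n, seed) {
  ord <- with_seed(seed, sample.int(n))
  ntr <- floor(0.8 * n); nva <- floor(0.1 * n)
  list(train = sort(ord[seq_len(ntr)]),
       val = sort(ord[ntr + seq_len(nva)]),
       test = sort(ord[setdiff(seq_len(n), seq_len(ntr + nva))]))
}

#' Simulate a paired sparse/dense dataset
#'
#' For each phantom seed: phantom generation, Monte-Carlo light transport,
#' initial pressure, forward projection to the dense array, transducer
#' band-limiting and low-pass conditioning, delay-and-sum reconstruction
#' with all elements (ground truth) and with each equidistantly
#' under-sampled count, ROI crop with coronal downsampling, and pair
#' normalization. Split assignment is deterministic from the master seed.
#'
#' @param spec a [dataset_spec()].
#' @param verbose print progress.
#' @return a manifest list: `spec`, `split` (train/val/test indices),
#'   `array` (dense geometry), `phantoms` (per phantom: `seed` and `pairs`,
#'   a named list of `paired_volume` per element count).
#' @export
simulate_dataset <- function(spec, verbose = FALSE) {
  grid <- spec$grid
  rgrid <- spec$recon_grid %||% grid
  ext <- grid_extent(grid)
  center_m <- c(ext[1] / 2, ext[2] / 2, spec$params$muscle_thickness) / 1000
  geom <- make_hemisphere_array(spec$dense_elements, spec$array_radius, center_m)
  medium <- medium_spec()
  timing <- default_timing(grid, geom, medium, fs = spec$fs)
  subs <- lapply(spec$element_counts, function(k) subsample_equidistant(geom, k))
  names(subs) <- as.character(spec$element_counts)
  phantoms <- vector("list", spec$n_phantoms)
  for (i in seq_len(spec$n_phantoms)) {
    sd_i <- seed_stream(spec$master_seed, i)
    if (verbose) message(sprintf("phantom %d/%d (seed %d)", i, spec$n_phantoms, sd_i))
    ph <- generate_phantom(sd_i, grid, spec$params)
    pr <- assign_optical_properties(ph)
    mc <- run_monte_carlo(pr$mu_a, pr$mu_s, pr$g, grid, spec$beam,
                          n_photons = spec$n_photons,
                          seed = seed_stream(spec$master_seed, 10000L + i))
    p0 <- initial_pressure(mc)
    cd <- forward_project(p0, geom, medium, timing)
    cd <- apply_transducer_response(cd, spec$f0, spec$fractional_bw)
    cd <- lowpass_filter(cd, spec$lowpass_cutoff)
    dense <- das_reconstruct(cd, rgrid)
    dense$provenance <- list(kind = "dense", elements = spec$dense_elements)
    # one crop window (from the dense volume) shared by all members
    dn <- crop_and_downsample(dense, spec$crop_shape)
    roi_center <- attr(dn, "roi_center")
    pairs <- list()
    for (k in names(subs)) {
      cds <- subset_channels(cd, subs[[k]])
      sp <- das_reconstruct(cds, rgrid)
      sp$provenance <- list(kind = "sparse", elements = as.integer(k))
      spn <- crop_and_downsample(sp, spec$crop_shape, center = roi_center)
      pairs[[k]] <- normalize_pair(spn, dn)
    }
    phantoms[[i]] <- list(seed = sd_i, pairs = pairs)
  }
  list(spec = spec, split = split_dataset(spec$n_phantoms, spec$master_seed),
       array = geom, phantoms = phantoms)
}

manifest_pairs <- function(manifest, idx, count) {
  lapply(manifest$phantoms[idx], function(p) p$pairs[[as.character(count)]])
}

#' Sparsity-sweep evaluation
#'
#' Mean 3D PSNR and MS-SSIM of the sparse inputs, and of the network
#' outputs when a model is supplied, against the dense ground truth for
#' every requested element count, with relative improvements
#' (dnn - sparse)/sparse in percent.
#'
#' @param pairs_by_count named list: element count -> list of
#'   `paired_volume`s (the test set).
#' @param model `resunet_fit`/`res_unet` or `NULL` (sparse-only report).
#' @param counts element counts to report (default: all in
#'   `pairs_by_count`); a missing count is an error.
#' @param patch,overlap tiled-inference settings.
#' @return data.frame of class `sweep_report` with columns count, cohort,
#'   psnr_db, ms_ssim, rel_improvement_psnr_pct, rel_improvement_msssim_pct.
#' @export
evaluate_sweep <- function(pairs_by_count, model = NULL, counts = NULL,
                           patch = 96L, overlap = NULL) {
  counts <- counts %||% as.integer(names(pairs_by_count))
  missing <- setdiff(as.character(counts), names(pairs_by_count))
  if (length(missing)) stopf("missing test pairs for counts: %s",
                             paste(missing, collapse = ", "))
  rows <- list()
  # volumes are min-max scaled individually before scoring: delay-and-sum
  # outputs are unnormalized sums, so amplitude scales with element count
  rescale01 <- function(v) {
    r <- range(v)
    if (diff(r) > 0) (v - r[1]) / diff(r) else v * 0
  }
  for (k in as.character(counts)) {
    prs <- pairs_by_count[[k]]
    sp_psnr <- sp_ms <- dn_psnr <- dn_ms <- numeric(length(prs))
    for (i in seq_along(prs)) {
      pr <- prs[[i]]
      dref <- rescale01(pr$dense)
      spn <- rescale01(pr$sparse)
      sp_psnr[i] <- psnr3d(spn, dref)
      sp_ms[i] <- ms_ssim3d(spn, dref)
      if (!is.null(model)) {
        dnn <- rescale01(as_values(infer_volume(model, pr$sparse, patch = patch,
                                                overlap = overlap)))
        dn_psnr[i] <- psnr3d(dnn, dref)
        dn_ms[i] <- ms_ssim3d(dnn, dref)
      }
    }
    rows[[k]] <- data.frame(count = as.integer(k), cohort = "sparse",
                            psnr_db = mean(sp_psnr), ms_ssim = mean(sp_ms),
                            rel_improvement_psnr_pct = NA_real_,
                            rel_improvement_msssim_pct = NA_real_)
    if (!is.null(model)) {
      rows[[paste0(k, "_dnn")]] <- data.frame(
        count = as.integer(k), cohort = "dnn",
        psnr_db = mean(dn_psnr), ms_ssim = mean(dn_ms),
        rel_improvement_psnr_pct = (mean(dn_psnr) - mean(sp_psnr)) / mean(sp_psnr) * 100,
        rel_improvement_msssim_pct = (mean(dn_ms) - mean(sp_ms)) / mean(sp_ms) * 100)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_report", "data.frame")
  out
}

#' Desk-scale end-to-end study
#'
#' Simulates a reduced paired dataset ([desk_dataset_spec()]), trains a
#' reduced Res-UNet (2 levels, 8 base channels, 32-voxel patches) on one
#' sparsity level, and evaluates the sparse inputs and network outputs on
#' the held-out test set, including a sparse-only sweep over element
#' counts.
#'
#' @param seed master seed for the whole study.
#' @param n_phantoms phantoms to simulate.
#' @param train_count sparse element count used for training pairs.
#' @param sweep_counts counts for the sparse-input sweep.
#' @param epochs training epochs.
#' @param levels,base_channels reduced model size.
#' @param patch training/inference patch side.
#' @param verbose print progress.
#' @return list: `fit`, `report` (dnn vs sparse at `train_count`),
#'   `sweep` (sparse-only over `sweep_counts`), and the per-count means.
#' @export
desk_study <- function(seed, n_phantoms = 20L, train_count = 128L,
                       sweep_counts = c(64L, 128L, 256L), epochs = 50L,
                       levels = 2L, base_channels = 8L, patch = 24L,
                       verbose = FALSE) {
  spec <- desk_dataset_spec(seed, n_phantoms,
                            element_counts = sort(unique(c(sweep_counts, train_count))))
  manifest <- simulate_dataset(spec, verbose = verbose)
  sp <- manifest$split
  train <- manifest_pairs(manifest, sp$train, train_count)
  val <- manifest_pairs(manifest, sp$val, train_count)
  model <- init_he_normal(res_unet(levels, base_channels), seed_stream(seed, 777L))
  cfg <- train_config(max_epochs = epochs, patch = patch,
                      seed = seed_stream(seed, 778L))
  fit <- train_resunet(train, val, model, cfg)
  test_by_count <- lapply(stats::setNames(sweep_counts, as.character(sweep_counts)),
                          function(k) manifest_pairs(manifest, sp$test, k))
  report <- evaluate_sweep(test_by_count[as.character(train_count)], fit,
                           patch = patch)
  sweep <- evaluate_sweep(test_by_count, model = NULL)
  list(fit = fit, report = report, sweep = sweep,
       msssim_sparse = report$ms_ssim[report$cohort == "sparse"],
       msssim_dnn = report$ms_ssim[report$cohort == "dnn"],
       psnr_sparse = report$psnr_db[report$cohort == "sparse"],
       psnr_dnn = report$psnr_db[report$cohort == "dnn"],
       split = sp)
}
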