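gauss_kernel1d <- function(window = 11L, sigma = 1.5) {
  hw <- (window - 1L) / 2
  k <- exp(-((-hw:hw)^2) / (2 * sigma^2))
  k / sum(k)
}

std_msssim_weights <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)

max_feasible_scales <- function(dims, window) {
  m <- min(dims)
  s <- 0L
  while ((window - 1) * 2^s + 1 <= m && s < 5L) s <- s + 1L
  s
}

# Shared MS-SSIM engine. Per scale: Gaussian local statistics (window
# `window`, sigma `sigma`, symmetric boundaries), contrast-structure term
# cs = (2*sxy + C2)/(sxx + syy + C2) averaged over voxels; the coarsest
# scale uses the full SSIM map (luminance times cs). Scales are linked by
# 2x average pooling. Value = prod(mean_j ^ w_j) with the standard scale
# weights renormalized to the number of scales used; means are clamped at
# a small positive floor before exponentiation. When `want_grad`, also
# returns d(value)/d(x) (the first argument), using the same Gaussian
# filter as the adjoint.
msssim_engine <- function(x, y, dims, scales, window, sigma, data_range, K,
                          want_grad = FALSE) {
  kern <- gauss_kernel1d(window, sigma)
  C1 <- (K[1] * data_range)^2
  C2 <- (K[2] * data_range)^2
  w <- std_msssim_weights[seq_len(scales)]
  w <- w / sum(w)
  eps <- 1e-8
  xs <- list(as.numeric(x)); ys <- list(as.numeric(y)); dd <- list(as.integer(dims))
  for (j in seq_len(scales - 1L)) {
    xs[[j + 1L]] <- cpp_avgpool2(xs[[j]], dd[[j]])
    ys[[j + 1L]] <- cpp_avgpool2(ys[[j]], dd[[j]])
    dd[[j + 1L]] <- dd[[j]] %/% 2L
  }
  tvals <- numeric(scales)
  cache <- vector("list", scales)
  for (j in seq_len(scales)) {
    xj <- xs[[j]]; yj <- ys[[j]]; dj <- dd[[j]]
    mx <- cpp_gauss3(xj, dj, kern); my <- cpp_gauss3(yj, dj, kern)
    sxx <- cpp_gauss3(xj * xj, dj, kern) - mx^2
    syy <- cpp_gauss3(yj * yj, dj, kern) - my^2
    sxy <- cpp_gauss3(xj * yj, dj, kern) - mx * my
    B2 <- sxx + syy + C2
    cs <- (2 * sxy + C2) / B2
    if (j < scales) {
      tvals[j] <- mean(cs)
      if (want_grad) cache[[j]] <- list(cs = cs, B2 = B2, mx = mx, my = my)
    } else {
      B1 <- mx^2 + my^2 + C1
      l <- (2 * mx * my + C1) / B1
      tvals[j] <- mean(l * cs)
      if (want_grad) cache[[j]] <- list(cs = cs, B2 = B2, mx = mx, my = my,
                                        l = l, B1 = B1)
    }
  }
  tc <- pmax(tvals, eps)
  value <- prod(tc^w)
  if (!want_grad) return(list(value = value, means = tvals))
  grad <- NULL
  for (j in seq_len(scales)) {
    if (tvals[j] <= eps) next
    dVdt <- value * w[j] / tc[j]
    cj <- cache[[j]]; dj <- dd[[j]]; xj <- xs[[j]]; yj <- ys[[j]]
    N <- prod(dj)
    if (j < scales) {
      f_mu <- NULL
      f_sxx <- -cj$cs / cj$B2
      f_sxy <- 2 / cj$B2
    } else {
      f_sxx <- -(cj$l * cj$cs) / cj$B2
      f_sxy <- 2 * cj$l / cj$B2
      f_mu <- cj$cs * (2 * cj$my - 2 * cj$mx * cj$l) / cj$B1
    }
    g <- 2 * xj * cpp_gauss3(f_sxx, dj, kern) -
      2 * cpp_gauss3(f_sxx * cj$mx, dj, kern) +
      yj * cpp_gauss3(f_sxy, dj, kern) -
      cpp_gauss3(f_sxy * cj$my, dj, kern)
    if (!is.null(f_mu)) g <- g + cpp_gauss3(f_mu, dj, kern)
    g <- g * (dVdt / N)
    for (k in rev(seq_len(j - 1L))) g <- cpp_avgpool2_bwd(g, dd[[k]])
    grad <- if (is.null(grad)) g else grad + g
  }
  if (is.null(grad)) grad <- numeric(prod(dims))
  list(value = value, means = tvals, grad = array(grad, dim = dims))
}

#' 3D multi-scale structural similarity
#'
#' MS-SSIM over dyadic scales with 3D Gaussian local windows: the
#' contrast-structure term at every scale and the luminance term at the
#' coarsest, exponentiated by the standard scale weights renormalized to
#' the number of scales used. Scales are linked by 2x average pooling.
#'
#' @param x,y volumes (3D arrays or `recon_volume`s) of identical shape.
#' @param scales number of scales; `NULL` uses the largest feasible number
#'   (at most 5) for the volume size. Requesting more than feasible is an
#'   error stating the maximum.
#' @param window odd Gaussian window width (voxels).
#' @param sigma Gaussian window sigma.
#' @param data_range value range of the inputs.
#' @param K stability constants (K1, K2).
#' @return MS-SSIM value in (0, 1]; 1 iff the volumes are identical.
#' @export
ms_ssim3d <- function(x, y, scales = NULL, window = 11L, sigma = 1.5,
                      data_range = 1, K = c(0.01, 0.03)) {
  xv <- as_values(x); yv <- as_values(y)
  if (!all(dim(xv) == dim(yv))) stopf("volumes must share a shape")
  feas <- max_feasible_scales(dim(xv), window)
  if (feas < 1L) stopf("volume too small for window %d", window)
  if (is.null(scales)) scales <- feas
  if (scales > feas)
    stopf("volume permits at most %d scales at window %d (requested %d)",
          feas, window, scales)
  msssim_engine(xv, yv, dim(xv), as.integer(scales), window, sigma,
                data_range, K)$value
}

#' 3D peak signal-to-noise ratio
#'
#' 10*log10(data_range^2 / MSE). Identical volumes (zero MSE) are reported
#' as the documented cap.
#'
#' @param x,y volumes of identical shape (`y` is the reference).
#' @param data_range peak-to-peak value range.
#' @param cap value (dB) reported when MSE = 0.
#' @return PSNR in dB.
#' @export
psnr3d <- function(x, y, data_range = 1, cap = 100) {
  xv <- as_values(x); yv <- as_values(y)
  if (!all(dim(xv) == dim(yv))) stopf("volumes must share a shape")
  if (data_range <= 0) stopf("data_range must be positive")
  mse <- mean((xv - yv)^2)
  if (mse == 0) return(cap)
  min(cap, 10 * log10(data_range^2 / mse))
}

#' Composite loss weights
#' @param w_mae weight of the mean-absolute-error term.
#' @param w_msssim weight of the (1 - MS-SSIM) term.
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(w_mae = 0.3, w_msssim = 0.7) {
  if (w_mae < 0 || w_msssim < 0) stopf("loss weights must be nonnegative")
  structure(list(w_mae = w_mae, w_msssim = w_msssim), class = "loss_weights")
}

#' Composite training loss: L1 plus multi-scale SSIM
#'
#' loss = w_mae * mean|pred - target| + w_msssim * (1 - MS-SSIM(pred,
#' target)). The MS-SSIM scale count is limited by the patch size (same
#' engine as [ms_ssim3d()]).
#'
#' @param pred,target patches of identical shape, values on a common range.
#' @param w a [loss_weights()]; defaults to (0.3, 0.7).
#' @param data_range value range used by the SSIM constants.
#' @return nonnegative scalar loss.
#' @export
composite_loss <- function(pred, target, w = loss_weights(), data_range = 1) {
  if (!all(dim(pred) == dim(target))) stopf("pred and target must share a shape")
  mae <- mean(abs(pred - target))
  ms <- if (w$w_msssim > 0) ms_ssim3d(pred, target, data_range = data_range) else 1
  w$w_mae * mae + w$w_msssim * (1 - ms)
}

# loss and gradient with respect to pred, for the training loop
composite_loss_grad <- function(pred, target, w = loss_weights(), data_range = 1) {
  d <- dim(pred)
  e <- pred - target
  mae <- mean(abs(e))
  g <- w$w_mae * sign(e) / length(e)
  loss <- w$w_mae * mae
  if (w$w_msssim > 0) {
    feas <- max_feasible_scales(d, 11L)
    ms <- msssim_engine(pred, target, d, feas, 11L, 1.5, data_range,
                        c(0.01, 0.03), want_grad = TRUE)
    loss <- loss + w$w_msssim * (1 - ms$value)
    g <- g - w$w_msssim * ms$grad
  }
  list(loss = loss, grad = g)
}
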