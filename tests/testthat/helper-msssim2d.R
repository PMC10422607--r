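# Independent plain-R 2D MS-SSIM reference (dimensional-reduction oracle for
# the 3D implementation on z-constant volumes). Deliberately written as a
# separate code path: explicit per-row/column filtering loops, no shared
# kernels with the package.

ref_gauss2d <- function(img, kern) {
  hw <- (length(kern) - 1) / 2
  n1 <- nrow(img); n2 <- ncol(img)
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i <- ifelse(i < 1, 1 - i, i)
      i <- ifelse(i > n, 2 * n + 1 - i, i)
    }
    i
  }
  tmp <- matrix(0, n1, n2)
  for (r in 1:n1) {
    idx <- refl(r + (-hw:hw), n1)
    tmp[r, ] <- colSums(img[idx, , drop = FALSE] * kern)
  }
  out <- matrix(0, n1, n2)
  for (cc in 1:n2) {
    idx <- refl(cc + (-hw:hw), n2)
    acc <- numeric(n1)
    for (j in seq_along(idx)) acc <- acc + tmp[, idx[j]] * kern[j]
    out[, cc] <- acc
  }
  out
}

ref_msssim2d <- function(x, y, scales, window = 11, sigma = 1.5,
                         K = c(0.01, 0.03), dr = 1) {
  kk <- exp(-((-(window - 1) / 2):((window - 1) / 2))^2 / (2 * sigma^2))
  kk <- kk / sum(kk)
  C1 <- (K[1] * dr)^2; C2 <- (K[2] * dr)^2
  wts <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)[1:scales]
  wts <- wts / sum(wts)
  vals <- numeric(scales)
  for (j in 1:scales) {
    mx <- ref_gauss2d(x, kk); my <- ref_gauss2d(y, kk)
    sxx <- ref_gauss2d(x * x, kk) - mx^2
    syy <- ref_gauss2d(y * y, kk) - my^2
    sxy <- ref_gauss2d(x * y, kk) - mx * my
    cs <- (2 * sxy + C2) / (sxx + syy + C2)
    if (j < scales) {
      vals[j] <- mean(cs)
      n1 <- floor(nrow(x) / 2); n2 <- floor(ncol(x) / 2)
      ds <- function(m) {
        (m[seq(1, 2 * n1, 2), seq(1, 2 * n2, 2)] +
         m[seq(2, 2 * n1, 2), seq(1, 2 * n2, 2)] +
         m[seq(1, 2 * n1, 2), seq(2, 2 * n2, 2)] +
         m[seq(2, 2 * n1, 2), seq(2, 2 * n2, 2)]) / 4
      }
      x <- ds(x); y <- ds(y)
    } else {
      vals[j] <- mean(((2 * mx * my + C1) / (mx^2 + my^2 + C1)) * cs)
    }
  }
  prod(pmax(vals, 1e-8)^wts)
}
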