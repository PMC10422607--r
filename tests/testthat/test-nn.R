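pa <- asNamespace("pabreast")

test_that("the network preserves shape for sides divisible by 2^levels", {
  m <- init_he_normal(res_unet(4L, 2L), 1L)
  x <- array(rnorm(96^3), dim = c(96, 96, 96))
  y <- predict(m, x)
  expect_identical(dim(y), dim(x))
  m2 <- init_he_normal(res_unet(2L, 4L), 1L)
  x2 <- array(rnorm(16 * 32 * 24), dim = c(16L, 32L, 24L))
  r <- pa$resunet_forward(m2, matrix(as.numeric(x2), ncol = 1), dim(x2))
  expect_equal(dim(r$out), c(length(x2), 1L))
  expect_error(pa$resunet_forward(m2, matrix(as.numeric(x2), ncol = 1), c(18L, 32L, 24L)),
               "divisible")
})

test_that("zeroed final convolution reduces the network to the identity", {
  m <- init_he_normal(res_unet(2L, 4L), 2L)
  m$params$final$out$W[] <- 0
  m$params$final$out$b[] <- 0
  x <- array(rnorm(16^3), dim = c(16, 16, 16))
  expect_identical(predict(m, x), x)
})

test_that("evaluation mode gives per-sample independent, repeatable outputs", {
  m <- init_he_normal(res_unet(2L, 4L), 3L)
  x <- array(rnorm(16^3), dim = c(16, 16, 16))
  y1 <- predict(m, x)
  stacked <- matrix(c(as.numeric(x), as.numeric(x)), ncol = 1)
  r <- pa$resunet_forward(m, stacked, dim(x), B = 2L, training = FALSE)
  expect_lt(max(abs(r$out[seq_len(4096), 1] - as.numeric(y1))), 1e-6)
  expect_lt(max(abs(r$out[4096 + seq_len(4096), 1] - r$out[seq_len(4096), 1])), 1e-6)
  expect_identical(predict(m, x), y1)
})

test_that("He initialization is seeded, zero-bias, with variance 2/fan_in", {
  m1 <- init_he_normal(res_unet(2L, 8L), 7L)
  m2 <- init_he_normal(res_unet(2L, 8L), 7L)
  expect_identical(m1$params, m2$params)
  W <- m1$params$enc[[2]]$conv1$W  # 3^3 kernel, 8 input channels
  fan_in <- 27 * 8
  expect_lt(abs(stats::var(as.numeric(W)) - 2 / fan_in) / (2 / fan_in), 0.1)
  expect_true(all(m1$params$enc[[1]]$conv1$b == 0))
  expect_true(all(m1$params$final$out$b == 0))
  expect_true(all(m1$params$enc[[1]]$bn1$gamma == 1))
})

test_that("analytic network gradients match finite differences", {
  set.seed(3)
  mg <- init_he_normal(res_unet(1L, 2L), 5L)
  xs <- matrix(rnorm(2 * 8^3), ncol = 1)
  ts <- rnorm(2 * 8^3)
  lossfn <- function(model) {
    fw <- pa$resunet_forward(model, xs, c(8L, 8L, 8L), B = 2L, training = TRUE)
    sum((fw$out - ts)^2) / 1024
  }
  fw <- pa$resunet_forward(mg, xs, c(8L, 8L, 8L), B = 2L, training = TRUE)
  gr <- pa$resunet_backward(fw$model, fw$cache, matrix(2 * (fw$out - ts) / 1024, ncol = 1))
  gflat <- pa$flatten_params(gr, trainable_only = TRUE)
  pflat <- pa$flatten_params(mg$params, trainable_only = TRUE)
  eps <- 1e-3
  set.seed(4)
  checked <- 0L
  for (nm in names(pflat)) {
    if (grepl("conv[12]\\.b$|conv\\.b$", nm)) next  # absorbed by batch norm
    i <- sample(length(pflat[[nm]]), 1)
    f <- pflat
    f[[nm]][i] <- f[[nm]][i] + eps
    mp <- mg; mp$params <- pa$assign_flat(mp$params, f)
    lp <- lossfn(mp)
    f[[nm]][i] <- f[[nm]][i] - 2 * eps
    mp$params <- pa$assign_flat(mp$params, f)
    lm <- lossfn(mp)
    num <- (lp - lm) / (2 * eps)
    ana <- gflat[[nm]][i]
    expect_lt(abs(num - ana), 2e-3 + 0.05 * (abs(num) + abs(ana)))
    checked <- checked + 1L
  }
  expect_gte(checked, 25L)
})

test_that("composite loss follows its closed forms and bounds", {
  x <- array(runif(24^3), dim = c(24, 24, 24))
  expect_equal(composite_loss(x, x), 0)
  # weights (1, 0) reduce to the mean absolute error
  y <- x + 0.05
  expect_equal(composite_loss(y, x, loss_weights(1, 0)), 0.05)
  expect_error(composite_loss(x, array(0, c(8, 8, 8))), "shape")
  # bounds on [0,1] inputs
  set.seed(8)
  for (k in 1:5) {
    a <- array(runif(16^3), dim = c(16, 16, 16))
    b <- array(runif(16^3), dim = c(16, 16, 16))
    l <- composite_loss(a, b)
    expect_gte(l, 0)
    expect_lte(l, 0.3 * 1 + 1.4)
  }
})

test_that("constant-offset composite loss matches the analytic MS-SSIM", {
  target <- array(0.4, dim = c(32, 32, 32))
  pred <- target + 0.1
  # constant volumes: all variances vanish, cs = 1 at every scale, and the
  # luminance term at the coarsest scale has the closed form below
  C1 <- 1e-4
  l <- (2 * 0.5 * 0.4 + C1) / (0.5^2 + 0.4^2 + C1)
  wts <- c(0.0448, 0.2856)
  wts <- wts / sum(wts)
  ms <- l^wts[2]  # two feasible scales at 32^3, luminance only at the last
  expect_equal(composite_loss(pred, target), 0.3 * 0.1 + 0.7 * (1 - ms),
               tolerance = 1e-10)
})

test_that("the loss gradient matches finite differences", {
  set.seed(9)
  xp <- array(runif(24^3), dim = c(24, 24, 24))
  tp <- array(runif(24^3), dim = c(24, 24, 24))
  lg <- pa$composite_loss_grad(xp, tp)
  expect_equal(lg$loss, composite_loss(xp, tp), tolerance = 1e-12)
  eps <- 1e-6
  for (k in 1:8) {
    i <- sample(length(xp), 1)
    xq <- xp; xq[i] <- xq[i] + eps
    lp <- composite_loss(xq, tp)
    xq[i] <- xq[i] - 2 * eps
    lm <- composite_loss(xq, tp)
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - lg$grad[i]), 1e-4 * max(1, abs(num)))
  }
})

test_that("checkpoints round-trip through a single file", {
  m <- init_he_normal(res_unet(2L, 4L), 11L)
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path), add = TRUE)
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  expect_identical(back$cfg, m$cfg)
})
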