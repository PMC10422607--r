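# 3D Res-UNet engine.
#
# Activations are (nvox x channels) matrices over a column-major voxel grid;
# a batch is a list of such matrices sharing `dims`. The network is an
# encoder-decoder with, per level, a unit of two basic modules
# (3^3 conv -> batch norm -> LeakyReLU) plus a 3^3 convolution shortcut
# added to the unit output; 2^3 max pooling between encoder levels, 2^3
# transposed convolutions in the decoder with channel concatenation of the
# encoder skip, a final basic module and 1x1x1 convolution, and a global
# input-to-output element-wise sum.

#' Construct a 3D Res-UNet model
#'
#' @param levels number of down/up-sampling steps; the encoder has
#'   `levels + 1` units (the deepest is the bottleneck). Input patch sides
#'   must be divisible by 2^levels.
#' @param base_channels channels of the first level; doubled per level.
#' @param leaky_slope negative slope of the LeakyReLU activations.
#' @return an object of class `res_unet` (untrained; weights are `NULL`
#'   until [init_he_normal()]).
#' @export
res_unet <- function(levels = 4L, base_channels = 32L, leaky_slope = 0.01) {
  levels <- as.integer(levels); base_channels <- as.integer(base_channels)
  if (levels < 1L || base_channels < 1L) stopf("levels and base_channels must be >= 1")
  if (leaky_slope <= 0) stopf("leaky_slope must be a small positive real")
  structure(list(cfg = list(levels = levels, base = base_channels,
                            slope = leaky_slope, in_ch = 1L),
                 params = NULL), class = "res_unet")
}

#' @export
print.res_unet <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("res_unet: levels=%d, base_channels=%d, leaky_slope=%g (%s)\n",
              cfg$levels, cfg$base, cfg$slope,
              if (is.null(x$params)) "uninitialized"
              else sprintf("%s trainable parameters",
                           format(n_trainable(x), big.mark = ","))))
  invisible(x)
}

enc_channels <- function(cfg) cfg$base * 2^(0:cfg$levels)

n_trainable <- function(model) {
  if (is.null(model$params)) return(0L)
  sum(vapply(flatten_params(model$params, trainable_only = TRUE), length, numeric(1)))
}

#' He-normal weight initialization
#'
#' Convolution weights are drawn from a zero-mean normal with variance
#' 2/fan_in; biases are zero; batch-norm scale/shift start at 1/0.
#' Deterministic given the seed.
#'
#' @param model a [res_unet()].
#' @param seed integer seed.
#' @return the model with initialized parameters.
#' @export
init_he_normal <- function(model, seed) {
  cfg <- model$cfg
  ch <- enc_channels(cfg)
  L <- cfg$levels
  make_conv <- function(cin, cout, k = 27L) {
    list(W = matrix(stats::rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))), k * cin, cout),
         b = numeric(cout))
  }
  make_tconv <- function(cin, cout) {
    list(W = matrix(stats::rnorm(cin * 8 * cout, sd = sqrt(2 / (8 * cin))), cin, 8 * cout),
         b = numeric(cout))
  }
  make_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c),
                              rm = numeric(c), rv = rep(1, c))
  make_unit <- function(cin, c) list(conv1 = make_conv(cin, c), bn1 = make_bn(c),
                                     conv2 = make_conv(c, c), bn2 = make_bn(c),
                                     sc = make_conv(cin, c))
  with_seed(seed, {
    enc <- vector("list", L + 1L)
    enc[[1L]] <- make_unit(cfg$in_ch, ch[1])
    for (l in seq_len(L)) enc[[l + 1L]] <- make_unit(ch[l], ch[l + 1])
    dec <- vector("list", L)
    for (l in seq_len(L)) {
      dec[[l]] <- list(tconv = make_tconv(ch[l + 1], ch[l]),
                       unit = make_unit(2L * ch[l], ch[l]))
    }
    final <- list(conv = make_conv(ch[1], ch[1]), bn = make_bn(ch[1]),
                  out = make_conv(ch[1], 1L, k = 1L))
    model$params <- list(enc = enc, dec = dec, final = final)
    model
  })
}

# ---- layer primitives ----
# Activations are stacked-batch (B*nvox x channels) matrices; sample b
# occupies the b-th block of rows.

bn_fwd <- function(bn, x, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    n <- nrow(x)
    mu <- colSums(x) / n
    va <- pmax(colSums(x * x) / n - mu^2, 0)
    invstd <- 1 / sqrt(va + eps)
    bn$rm <- (1 - momentum) * bn$rm + momentum * mu
    bn$rv <- (1 - momentum) * bn$rv + momentum * va
  } else {
    mu <- bn$rm
    invstd <- 1 / sqrt(bn$rv + eps)
  }
  out <- cpp_bn_apply(x, mu, invstd, bn$gamma, bn$beta)
  list(out = out, bn = bn, cache = list(x = x, mu = mu, invstd = invstd))
}

bn_bwd <- function(bn, cache, dy) {
  r <- cpp_bn_bwd(dy, cache$x, cache$mu, cache$invstd, bn$gamma)
  list(dx = r$dX, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}

unit_fwd <- function(u, x, dims, B, training, slope) {
  c1 <- cpp_conv3d_fwd(x, dims, B, u$conv1$W, u$conv1$b)
  b1 <- bn_fwd(u$bn1, c1, training); u$bn1 <- b1$bn
  r1 <- cpp_lrelu_fwd(b1$out, slope)
  c2 <- cpp_conv3d_fwd(r1, dims, B, u$conv2$W, u$conv2$b)
  b2 <- bn_fwd(u$bn2, c2, training); u$bn2 <- b2$bn
  r2 <- cpp_lrelu_fwd(b2$out, slope)
  out <- r2 + cpp_conv3d_fwd(x, dims, B, u$sc$W, u$sc$b)
  list(out = out, params = u,
       cache = list(x = x, bn1 = b1, r1 = r1, bn2 = b2, dims = dims, B = B))
}

unit_bwd <- function(u, cache, dout, slope) {
  dims <- cache$dims; B <- cache$B
  gsc <- cpp_conv3d_bwd(dout, cache$x, dims, B, u$sc$W)
  dr2 <- cpp_lrelu_bwd(dout, cache$bn2$out, slope)
  gb2 <- bn_bwd(u$bn2, cache$bn2$cache, dr2)
  gc2 <- cpp_conv3d_bwd(gb2$dx, cache$r1, dims, B, u$conv2$W)
  dr1 <- cpp_lrelu_bwd(gc2$dX, cache$bn1$out, slope)
  gb1 <- bn_bwd(u$bn1, cache$bn1$cache, dr1)
  gc1 <- cpp_conv3d_bwd(gb1$dx, cache$x, dims, B, u$conv1$W)
  dx <- gc1$dX + gsc$dX
  grads <- list(conv1 = list(W = gc1$dW, b = as.numeric(gc1$db)),
                bn1 = list(gamma = gb1$dgamma, beta = gb1$dbeta),
                conv2 = list(W = gc2$dW, b = as.numeric(gc2$db)),
                bn2 = list(gamma = gb2$dgamma, beta = gb2$dbeta),
                sc = list(W = gsc$dW, b = as.numeric(gsc$db)))
  list(dx = dx, grads = grads)
}

# ---- full network ----

resunet_forward <- function(model, x, dims, B = 1L, training = FALSE) {
  cfg <- model$cfg; p <- model$params
  if (is.null(p)) stopf("model has no weights; call init_he_normal() first")
  L <- cfg$levels
  if (any(dims %% 2^L != 0))
    stopf("input sides (%s) must be divisible by 2^levels = %d",
          paste(dims, collapse = "x"), 2^L)
  cache <- list(input = x, dims = dims, B = B)
  skips <- vector("list", L)
  cur <- x; curd <- dims
  for (l in seq_len(L)) {
    r <- unit_fwd(p$enc[[l]], cur, curd, B, training, cfg$slope)
    p$enc[[l]] <- r$params
    skips[[l]] <- r$out
    cache$enc[[l]] <- r$cache
    mp <- cpp_maxpool3d(r$out, curd, B)
    cache$idx[[l]] <- mp$idx
    cache$poolrows[[l]] <- nrow(r$out)
    cur <- mp$Y
    curd <- curd %/% 2L
  }
  r <- unit_fwd(p$enc[[L + 1L]], cur, curd, B, training, cfg$slope)
  p$enc[[L + 1L]] <- r$params
  cache$bott <- r$cache
  cur <- r$out
  for (l in rev(seq_len(L))) {
    up <- cpp_tconv3d_fwd(cur, curd, B, p$dec[[l]]$tconv$W, p$dec[[l]]$tconv$b)
    cache$dec[[l]] <- list(tin = cur, tdims = curd)
    curd <- curd * 2L
    r <- unit_fwd(p$dec[[l]]$unit, cbind(up, skips[[l]]), curd, B, training, cfg$slope)
    p$dec[[l]]$unit <- r$params
    cache$dec[[l]]$unit <- r$cache
    cur <- r$out
  }
  cf <- cpp_conv3d_fwd(cur, curd, B, p$final$conv$W, p$final$conv$b)
  bf <- bn_fwd(p$final$bn, cf, training); p$final$bn <- bf$bn
  rf <- cpp_lrelu_fwd(bf$out, cfg$slope)
  out <- rf %*% p$final$out$W + p$final$out$b[1] + x
  cache$final <- list(fin = cur, bn = bf, f = rf)
  model$params <- p
  list(out = out, model = model, cache = cache)
}

resunet_backward <- function(model, cache, dout) {
  cfg <- model$cfg; p <- model$params; L <- cfg$levels
  B <- cache$B
  ch <- enc_channels(cfg)
  g <- list(enc = vector("list", L + 1L), dec = vector("list", L), final = NULL)
  fc <- cache$final
  dW_out <- t(fc$f) %*% dout
  db_out <- colSums(dout)
  df <- dout %*% t(p$final$out$W)
  drf <- cpp_lrelu_bwd(df, fc$bn$out, cfg$slope)
  gbf <- bn_bwd(p$final$bn, fc$bn$cache, drf)
  gcf <- cpp_conv3d_bwd(gbf$dx, fc$fin, cache$dims, B, p$final$conv$W)
  g$final <- list(conv = list(W = gcf$dW, b = as.numeric(gcf$db)),
                  bn = list(gamma = gbf$dgamma, beta = gbf$dbeta),
                  out = list(W = dW_out, b = as.numeric(db_out)))
  dcur <- gcf$dX
  dskips <- vector("list", L)
  for (l in seq_len(L)) {
    r <- unit_bwd(p$dec[[l]]$unit, cache$dec[[l]]$unit, dcur, cfg$slope)
    g$dec[[l]]$unit <- r$grads
    cl <- ch[l]
    dup <- r$dx[, seq_len(cl), drop = FALSE]
    dskips[[l]] <- r$dx[, cl + seq_len(cl), drop = FALSE]
    tr <- cpp_tconv3d_bwd(dup, cache$dec[[l]]$tin, cache$dec[[l]]$tdims, B,
                          p$dec[[l]]$tconv$W)
    g$dec[[l]]$tconv <- list(W = tr$dW, b = as.numeric(tr$db))
    dcur <- tr$dX
  }
  r <- unit_bwd(p$enc[[L + 1L]], cache$bott, dcur, cfg$slope)
  g$enc[[L + 1L]] <- r$grads
  dpool <- r$dx
  for (l in rev(seq_len(L))) {
    dout_l <- cpp_maxpool3d_bwd(dpool, cache$idx[[l]], cache$poolrows[[l]]) + dskips[[l]]
    r <- unit_bwd(p$enc[[l]], cache$enc[[l]], dout_l, cfg$slope)
    g$enc[[l]] <- r$grads
    dpool <- r$dx
  }
  g
}

# ---- parameter flattening and Adam ----

flatten_params <- function(p, prefix = "", trainable_only = FALSE) {
  out <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (is.null(nms) || nms[i] == "") as.character(i) else nms[i]
        walk(x[[i]], paste0(path, ".", nm))
      }
    } else if (is.numeric(x)) {
      leaf <- sub("^\\.", "", path)
      if (trainable_only && grepl("\\.(rm|rv)$", leaf)) return(invisible())
      out[[leaf]] <<- x
    }
  }
  walk(p, prefix)
  out
}

assign_flat <- function(p, flat) {
  for (nm in names(flat)) {
    keys <- strsplit(nm, ".", fixed = TRUE)[[1]]
    path <- lapply(keys, function(k) if (grepl("^[0-9]+$", k)) as.integer(k) else k)
    p <- assign_nested(p, path, flat[[nm]])
  }
  p
}

assign_nested <- function(x, path, value) {
  if (length(path) == 1L) { x[[path[[1]]]] <- value; return(x) }
  x[[path[[1]]]] <- assign_nested(x[[path[[1]]]], path[-1L], value)
  x
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0), v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(flat, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(flat)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    gr <- gr + weight_decay * flat[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    flat[[nm]] <- flat[[nm]] - lr * (state$m[[nm]] / b1t) /
      (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(flat = flat, state = state)
}

#' Apply a Res-UNet to patches or volumes
#'
#' Runs the network in evaluation mode (batch-norm running statistics).
#' Inputs whose sides are divisible by 2^levels are processed in one
#' forward pass; larger or indivisible volumes are tiled into patches,
#' processed, and re-assembled with Gaussian-weighted stitching via
#' [infer_volume()].
#'
#' @param object a `res_unet` with initialized weights (or a `resunet_fit`).
#' @param newdata 3D array or `recon_volume`.
#' @param patch patch side for tiled inference (`NULL`: single pass if the
#'   shape permits, else 96).
#' @param ... unused.
#' @return 3D array with the shape of the input.
#' @export
predict.res_unet <- function(object, newdata, patch = NULL, ...) {
  x <- as_values(newdata)
  L <- object$cfg$levels
  if (is.null(patch) && all(dim(x) %% 2^L == 0) && all(dim(x) <= 128)) {
    r <- resunet_forward(object, matrix(as.numeric(x), ncol = 1), dim(x),
                         B = 1L, training = FALSE)
    return(array(r$out, dim = dim(x)))
  }
  infer_volume(object, x, patch = patch %||% 96L)
}
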