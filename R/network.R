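# Displacement-predicting ConvNet: a U-shaped encoder-decoder over
# (nx,ny,nz,channels) tensors with multi-kernel inception modules on the skip
# paths. Forward and backward passes are written out explicitly (there is no
# autograd); every layer caches what its gradient needs. The backward pass is
# verified against numerical differentiation in the tests.

#' Network configuration
#'
#' Describes the displacement-predicting ConvNet: three stride-2 encoder
#' stages (spatial reduction to (1/2)^3), an inception module on each skip
#' path (parallel convolutions with `inception_kernels`, concatenated, then a
#' 1-kernel channel-reducing convolution), three transposed-convolution
#' decoder stages with skip concatenation, and a final linear 3-channel
#' convolution. LeakyReLU follows every convolution block except the linear
#' head; batch normalization (over the spatial extent, batch size 1) sits
#' between convolution and activation when `use_batch_norm` is `TRUE`.
#'
#' @param input_shape integer length-3; every dimension divisible by 8.
#' @param enc_channels integer length-3: channels after each encoder stage.
#' @param inception_kernels odd kernel sizes of the parallel inception
#'   branches.
#' @param leaky_slope LeakyReLU negative slope.
#' @param use_batch_norm logical.
#' @return an object of class `lw_net_config`.
#' @export
network_config <- function(input_shape,
                           enc_channels = c(16L, 32L, 64L),
                           inception_kernels = c(1L, 3L, 5L),
                           leaky_slope = 0.2,
                           use_batch_norm = TRUE) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape %% 8L != 0L) ||
      any(input_shape < 8L))
    stop("every input_shape dimension must be a positive multiple of 8",
         call. = FALSE)
  enc_channels <- as.integer(enc_channels)
  if (length(enc_channels) != 3L || any(enc_channels < 1L))
    stop("enc_channels must be 3 positive integers", call. = FALSE)
  inception_kernels <- as.integer(inception_kernels)
  if (!length(inception_kernels) || any(inception_kernels %% 2L == 0L) ||
      any(inception_kernels < 1L))
    stop("inception kernels must be odd positive integers", call. = FALSE)
  structure(list(input_shape = input_shape, enc_channels = enc_channels,
                 inception_kernels = inception_kernels,
                 leaky_slope = leaky_slope,
                 use_batch_norm = isTRUE(use_batch_norm)),
            class = "lw_net_config")
}

# ---------------------------------------------------------------------------
# parameter initialization

init_conv <- function(k, cin, cout, sd = sqrt(2 / (k^3 * cin)), bn = TRUE) {
  p <- list(w = array(stats::rnorm(k^3 * cin * cout, 0, sd),
                      c(k, k, k, cin, cout)),
            b = numeric(cout))
  if (bn) { p$gamma <- rep(1, cout); p$beta <- numeric(cout) }
  p
}

# transposed convolution: the kernel keeps the conv orientation
# (k,k,k, out_big, in_small) because the forward pass is the conv adjoint,
# but bias and batch norm act on the upsampled (out_big) channels
init_convt <- function(k, cin_small, cout_big, bn = TRUE) {
  p <- list(w = array(stats::rnorm(k^3 * cout_big * cin_small, 0,
                                   sqrt(2 / (k^3 * cin_small))),
                      c(k, k, k, cout_big, cin_small)),
            b = numeric(cout_big))
  if (bn) { p$gamma <- rep(1, cout_big); p$beta <- numeric(cout_big) }
  p
}

init_inception <- function(kernels, ch, bn) {
  list(branches = lapply(kernels, function(k) init_conv(k, ch, ch, bn = bn)),
       reduce = init_conv(1L, length(kernels) * ch, ch, bn = bn))
}

init_network_params <- function(cfg) {
  c1 <- cfg$enc_channels[1]; c2 <- cfg$enc_channels[2]; c3 <- cfg$enc_channels[3]
  bn <- cfg$use_batch_norm
  list(
    stem  = init_conv(3L, 2L, c1, bn = bn),
    down1 = init_conv(3L, c1, c2, bn = bn),
    down2 = init_conv(3L, c2, c3, bn = bn),
    down3 = init_conv(3L, c3, c3, bn = bn),
    incep0 = init_inception(cfg$inception_kernels, c1, bn),
    incep1 = init_inception(cfg$inception_kernels, c2, bn),
    incep2 = init_inception(cfg$inception_kernels, c3, bn),
    up3 = init_convt(3L, c3, c3, bn = bn),
    fuse3 = init_conv(3L, 2L * c3, c3, bn = bn),
    up2 = init_convt(3L, c3, c2, bn = bn),
    fuse2 = init_conv(3L, 2L * c2, c2, bn = bn),
    up1 = init_convt(3L, c2, c1, bn = bn),
    fuse1 = init_conv(3L, 2L * c1, c1, bn = bn),
    # near-identity start: tiny weights so the initial field is almost zero
    head = init_conv(3L, c1, 3L, sd = 1e-3, bn = FALSE)
  )
}

#' Build the displacement-predicting network
#'
#' Allocates and initializes all trainable parameters (He-style for the
#' hidden convolutions; the final linear convolution starts near zero so the
#' untrained network predicts an almost-identity transform).
#'
#' @param cfg an [network_config()].
#' @param seed optional integer; when given, initialization is reproducible.
#' @return an object of class `lw_network` (configuration + parameter tree).
#' @export
build_network <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "lw_net_config"))
  params <- if (is.null(seed)) init_network_params(cfg)
            else with_seed(seed, init_network_params(cfg))
  structure(list(cfg = cfg, params = params), class = "lw_network")
}

#' Count trainable parameters
#' @param net an `lw_network`.
#' @return integer total of all trainable scalars.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "lw_network"))
  count <- function(x) {
    if (is.null(x)) 0
    else if (is.list(x)) sum(vapply(x, count, numeric(1)))
    else length(x)
  }
  as.integer(count(net$params))
}

#' @export
print.lw_network <- function(x, ...) {
  cat(sprintf("<lw_network> input %s, channels (%s), inception kernels (%s), %s parameters\n",
              paste(x$cfg$input_shape, collapse = "x"),
              paste(x$cfg$enc_channels, collapse = ", "),
              paste(x$cfg$inception_kernels, collapse = ", "),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# layer primitives (forward + backward)

lrelu_fwd <- function(a, slope) ifelse(a > 0, a, slope * a)
lrelu_bwd <- function(a, gy, slope) gy * ifelse(a > 0, 1, slope)

bn_fwd <- function(z, gamma, beta, eps = 1e-5) {
  d <- dim(z); nc <- d[4]
  if (prod(d[1:3]) == 1L) {
    # a singleton spatial extent has no statistics to normalize with
    # (x - mean(x) is identically zero); apply the affine part only
    y <- z
    for (c in seq_len(nc)) y[, , , c] <- gamma[c] * z[, , , c] + beta[c]
    return(list(y = y, xhat = z, inv = NULL, passthrough = TRUE))
  }
  y <- z
  xhat <- z
  inv <- numeric(nc)
  for (c in seq_len(nc)) {
    x <- z[, , , c]
    mu <- mean(x)
    v <- mean((x - mu)^2)
    inv[c] <- 1 / sqrt(v + eps)
    xh <- (x - mu) * inv[c]
    xhat[, , , c] <- xh
    y[, , , c] <- gamma[c] * xh + beta[c]
  }
  list(y = y, xhat = xhat, inv = inv)
}

bn_bwd <- function(cache, gamma, gy) {
  d <- dim(gy); nc <- d[4]; n <- prod(d[1:3])
  gz <- gy
  ggamma <- numeric(nc); gbeta <- numeric(nc)
  if (isTRUE(cache$passthrough)) {
    for (c in seq_len(nc)) {
      ggamma[c] <- sum(gy[, , , c] * cache$xhat[, , , c])
      gbeta[c] <- sum(gy[, , , c])
      gz[, , , c] <- gy[, , , c] * gamma[c]
    }
    return(list(gz = gz, ggamma = ggamma, gbeta = gbeta))
  }
  for (c in seq_len(nc)) {
    g <- gy[, , , c]
    xh <- cache$xhat[, , , c]
    ggamma[c] <- sum(g * xh)
    gbeta[c] <- sum(g)
    gxh <- g * gamma[c]
    gz[, , , c] <- cache$inv[c] / n *
      (n * gxh - sum(gxh) - xh * sum(gxh * xh))
  }
  list(gz = gz, ggamma = ggamma, gbeta = gbeta)
}

conv_block_fwd <- function(p, x, k, stride, pad, slope, use_bn, act = TRUE) {
  z <- .conv3d_fwd_cpp(x, p$w, p$b, stride, pad)
  bn <- NULL
  a <- z
  if (use_bn && !is.null(p$gamma)) {
    bn <- bn_fwd(z, p$gamma, p$beta)
    a <- bn$y
  }
  y <- if (act) lrelu_fwd(a, slope) else a
  list(y = y, cache = list(x = x, a = a, bn = bn))
}

conv_block_bwd <- function(p, cache, gy, k, stride, pad, slope, use_bn,
                           act = TRUE) {
  ga <- if (act) lrelu_bwd(cache$a, gy, slope) else gy
  gp <- list()
  if (use_bn && !is.null(p$gamma)) {
    bb <- bn_bwd(cache$bn, p$gamma, ga)
    gz <- bb$gz
    gp$gamma <- bb$ggamma
    gp$beta <- bb$gbeta
  } else gz <- ga
  d <- dim(cache$x)
  gp$w <- .conv3d_bwd_weight_cpp(cache$x, gz, k, stride, pad)
  gp$b <- apply(gz, 4, sum)
  gx <- .conv3d_bwd_input_cpp(gz, p$w, stride, pad, d[1], d[2], d[3])
  list(gx = gx, gp = gp[c("w", "b", "gamma", "beta")])
}

# transposed convolution (stride 2, pad 1): the adjoint of the stride-2
# encoder convolution, so spatial dimensions exactly double
convt_block_fwd <- function(p, x, out_sp, slope, use_bn, act = TRUE) {
  z <- .conv3d_bwd_input_cpp(x, p$w, 2L, 1L, out_sp[1], out_sp[2], out_sp[3])
  z <- sweep(z, 4, p$b, `+`)
  bn <- NULL
  a <- z
  if (use_bn && !is.null(p$gamma)) {
    bn <- bn_fwd(z, p$gamma, p$beta)
    a <- bn$y
  }
  y <- if (act) lrelu_fwd(a, slope) else a
  list(y = y, cache = list(x = x, a = a, bn = bn))
}

convt_block_bwd <- function(p, cache, gy, slope, use_bn, act = TRUE) {
  ga <- if (act) lrelu_bwd(cache$a, gy, slope) else gy
  gp <- list()
  if (use_bn && !is.null(p$gamma)) {
    bb <- bn_bwd(cache$bn, p$gamma, ga)
    gz <- bb$gz
    gp$gamma <- bb$ggamma
    gp$beta <- bb$gbeta
  } else gz <- ga
  # roles swap: the full-resolution gradient plays the conv input
  gp$w <- .conv3d_bwd_weight_cpp(gz, cache$x, 3L, 2L, 1L)
  gp$b <- apply(gz, 4, sum)
  gx <- .conv3d_fwd_cpp(gz, p$w, NULL, 2L, 1L)
  list(gx = gx, gp = gp[c("w", "b", "gamma", "beta")])
}

inception_fwd <- function(p, x, kernels, slope, use_bn) {
  branches <- vector("list", length(kernels))
  caches <- vector("list", length(kernels))
  for (j in seq_along(kernels)) {
    k <- kernels[j]
    r <- conv_block_fwd(p$branches[[j]], x, k, 1L, (k - 1L) %/% 2L,
                        slope, use_bn)
    branches[[j]] <- r$y
    caches[[j]] <- r$cache
  }
  catted <- do.call(cat4, branches)
  red <- conv_block_fwd(p$reduce, catted, 1L, 1L, 0L, slope, use_bn)
  list(y = red$y,
       cache = list(branches = caches, reduce = red$cache,
                    sizes = vapply(branches, function(b) dim(b)[4], integer(1))))
}

inception_bwd <- function(p, cache, gy, kernels, slope, use_bn) {
  red <- conv_block_bwd(p$reduce, cache$reduce, gy, 1L, 1L, 0L, slope, use_bn)
  gparts <- split4(red$gx, cache$sizes)
  gx <- NULL
  gp <- list(branches = vector("list", length(kernels)))
  for (j in seq_along(kernels)) {
    k <- kernels[j]
    bb <- conv_block_bwd(p$branches[[j]], cache$branches[[j]], gparts[[j]],
                         k, 1L, (k - 1L) %/% 2L, slope, use_bn)
    gx <- if (is.null(gx)) bb$gx else gx + bb$gx
    gp$branches[[j]] <- bb$gp
  }
  gp$reduce <- red$gp
  list(gx = gx, gp = gp)
}

# ---------------------------------------------------------------------------
# whole-network forward / backward

nn_forward <- function(params, cfg, x) {
  sl <- cfg$leaky_slope; bn <- cfg$use_batch_norm; ik <- cfg$inception_kernels
  sp <- dim(x)[1:3]
  if (any(sp %% 8L != 0L))
    stop("network input dimensions must be multiples of 8", call. = FALSE)
  e0 <- conv_block_fwd(params$stem, x, 3L, 1L, 1L, sl, bn)
  e1 <- conv_block_fwd(params$down1, e0$y, 3L, 2L, 1L, sl, bn)
  e2 <- conv_block_fwd(params$down2, e1$y, 3L, 2L, 1L, sl, bn)
  bt <- conv_block_fwd(params$down3, e2$y, 3L, 2L, 1L, sl, bn)
  s0 <- inception_fwd(params$incep0, e0$y, ik, sl, bn)
  s1 <- inception_fwd(params$incep1, e1$y, ik, sl, bn)
  s2 <- inception_fwd(params$incep2, e2$y, ik, sl, bn)
  u3 <- convt_block_fwd(params$up3, bt$y, sp %/% 4L, sl, bn)
  f3 <- conv_block_fwd(params$fuse3, cat4(u3$y, s2$y), 3L, 1L, 1L, sl, bn)
  u2 <- convt_block_fwd(params$up2, f3$y, sp %/% 2L, sl, bn)
  f2 <- conv_block_fwd(params$fuse2, cat4(u2$y, s1$y), 3L, 1L, 1L, sl, bn)
  u1 <- convt_block_fwd(params$up1, f2$y, sp, sl, bn)
  f1 <- conv_block_fwd(params$fuse1, cat4(u1$y, s0$y), 3L, 1L, 1L, sl, bn)
  hd <- conv_block_fwd(params$head, f1$y, 3L, 1L, 1L, sl, bn, act = FALSE)
  list(field = hd$y,
       cache = list(e0 = e0$cache, e1 = e1$cache, e2 = e2$cache,
                    bt = bt$cache, s0 = s0$cache, s1 = s1$cache,
                    s2 = s2$cache, u3 = u3$cache, f3 = f3$cache,
                    u2 = u2$cache, f2 = f2$cache, u1 = u1$cache,
                    f1 = f1$cache, hd = hd$cache,
                    ch = list(u3 = dim(u3$y)[4], s2 = dim(s2$y)[4],
                              u2 = dim(u2$y)[4], s1 = dim(s1$y)[4],
                              u1 = dim(u1$y)[4], s0 = dim(s0$y)[4])))
}

nn_backward <- function(params, cfg, cache, gfield) {
  sl <- cfg$leaky_slope; bn <- cfg$use_batch_norm; ik <- cfg$inception_kernels
  g <- list()
  hd <- conv_block_bwd(params$head, cache$hd, gfield, 3L, 1L, 1L, sl, bn,
                       act = FALSE)
  g$head <- hd$gp
  f1 <- conv_block_bwd(params$fuse1, cache$f1, hd$gx, 3L, 1L, 1L, sl, bn)
  g$fuse1 <- f1$gp
  p1 <- split4(f1$gx, c(cache$ch$u1, cache$ch$s0))
  u1 <- convt_block_bwd(params$up1, cache$u1, p1[[1]], sl, bn)
  g$up1 <- u1$gp
  s0 <- inception_bwd(params$incep0, cache$s0, p1[[2]], ik, sl, bn)
  g$incep0 <- s0$gp
  f2 <- conv_block_bwd(params$fuse2, cache$f2, u1$gx, 3L, 1L, 1L, sl, bn)
  g$fuse2 <- f2$gp
  p2 <- split4(f2$gx, c(cache$ch$u2, cache$ch$s1))
  u2 <- convt_block_bwd(params$up2, cache$u2, p2[[1]], sl, bn)
  g$up2 <- u2$gp
  s1 <- inception_bwd(params$incep1, cache$s1, p2[[2]], ik, sl, bn)
  g$incep1 <- s1$gp
  f3 <- conv_block_bwd(params$fuse3, cache$f3, u2$gx, 3L, 1L, 1L, sl, bn)
  g$fuse3 <- f3$gp
  p3 <- split4(f3$gx, c(cache$ch$u3, cache$ch$s2))
  u3 <- convt_block_bwd(params$up3, cache$u3, p3[[1]], sl, bn)
  g$up3 <- u3$gp
  s2 <- inception_bwd(params$incep2, cache$s2, p3[[2]], ik, sl, bn)
  g$incep2 <- s2$gp
  bt <- conv_block_bwd(params$down3, cache$bt, u3$gx, 3L, 2L, 1L, sl, bn)
  g$down3 <- bt$gp
  # encoder activations feed both the next stage and their skip inception
  e2 <- conv_block_bwd(params$down2, cache$e2, bt$gx + s2$gx, 3L, 2L, 1L,
                       sl, bn)
  g$down2 <- e2$gp
  e1 <- conv_block_bwd(params$down1, cache$e1, e2$gx + s1$gx, 3L, 2L, 1L,
                       sl, bn)
  g$down1 <- e1$gp
  e0 <- conv_block_bwd(params$stem, cache$e0, e1$gx + s0$gx, 3L, 1L, 1L,
                       sl, bn)
  g$stem <- e0$gp
  g
}

#' Predict the displacement field for one preprocessed pair
#'
#' Concatenates (moving, fixed) into the network's two input channels and
#' runs one forward pass.
#'
#' @param net an `lw_network`.
#' @param moving,fixed volumes or 3D arrays on a common grid with dimensions
#'   divisible by 8.
#' @return X x Y x Z x 3 displacement array (voxel units).
#' @export
predict_field <- function(net, moving, fixed) {
  stopifnot(inherits(net, "lw_network"))
  m <- vol_data(moving); f <- vol_data(fixed)
  if (!all(dim(m) == dim(f))) stop("pair shape mismatch", call. = FALSE)
  x <- array(c(m, f), c(dim(m), 2L))
  nn_forward(net$params, net$cfg, x)$field
}

#' Save / load a network checkpoint
#'
#' The checkpoint is an RDS file holding the configuration, the parameter
#' tree and any extra metadata, with a human-readable YAML sidecar of the
#' configuration.
#'
#' @param net an `lw_network`.
#' @param path checkpoint path (`.rds`).
#' @param extra optional list stored alongside (e.g. training weights).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path, extra = list()) {
  stopifnot(inherits(net, "lw_network"))
  saveRDS(list(cfg = unclass(net$cfg), params = net$params, extra = extra),
          path)
  yaml::write_yaml(
    c(unclass(net$cfg), list(n_parameters = count_parameters(net))),
    paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  net <- structure(list(cfg = structure(obj$cfg, class = "lw_net_config"),
                        params = obj$params),
                   class = "lw_network")
  attr(net, "extra") <- obj$extra
  net
}
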