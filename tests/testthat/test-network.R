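test_that("the network maps 2 channels to a 3-channel field of equal shape", {
  for (shape in list(c(8, 8, 8), c(16, 8, 16))) {
    cfg <- network_config(shape, enc_channels = c(2, 3, 4),
                          inception_kernels = c(1, 3))
    net <- build_network(cfg, seed = 1)
    f <- predict_field(net, rand_vol(shape, 1), rand_vol(shape, 2))
    expect_equal(dim(f), c(shape, 3L))
    expect_true(all(is.finite(f)))
  }
})

test_that("a fresh network can output negative values (linear head)", {
  cfg <- network_config(c(8, 8, 8), enc_channels = c(3, 4, 5),
                        inception_kernels = c(1, 3))
  # with a non-degenerate head the linear activation admits both signs
  net <- build_network(cfg, seed = 4)
  net$params$head$w <- net$params$head$w * 100
  f <- predict_field(net, rand_vol(c(8, 8, 8), 3), rand_vol(c(8, 8, 8), 4))
  expect_lt(min(f), 0)
  expect_gt(max(f), 0)
})

test_that("count_parameters matches the closed-form architecture arithmetic", {
  c1 <- 2L; c2 <- 3L; c3 <- 4L; ks <- c(1L, 3L)
  cfg <- network_config(c(8, 8, 8), enc_channels = c(c1, c2, c3),
                        inception_kernels = ks)
  net <- build_network(cfg, seed = 1)
  conv_n <- function(k, ci, co, bn = TRUE) k^3 * ci * co + co + if (bn) 2 * co else 0
  # transposed conv: kernel couples the same channel pair, but bias and batch
  # norm act on the upsampled output channels
  convt_n <- function(cin, cout) 3^3 * cin * cout + cout + 2 * cout
  incep_n <- function(ch) sum(vapply(ks, conv_n, numeric(1), ci = ch, co = ch)) +
    conv_n(1, length(ks) * ch, ch)
  want <- conv_n(3, 2, c1) + conv_n(3, c1, c2) + conv_n(3, c2, c3) +
    conv_n(3, c3, c3) +                       # encoder
    incep_n(c1) + incep_n(c2) + incep_n(c3) + # skip inceptions
    convt_n(c3, c3) + conv_n(3, 2 * c3, c3) +    # up3 + fuse3
    convt_n(c3, c2) + conv_n(3, 2 * c2, c2) +    # up2 + fuse2
    convt_n(c2, c1) + conv_n(3, 2 * c1, c1) +    # up1 + fuse1
    conv_n(3, c1, 3, bn = FALSE)                 # linear head
  expect_identical(count_parameters(net), as.integer(want))
})

test_that("the parameter count is invariant to the input shape", {
  a <- build_network(network_config(c(8, 8, 8), enc_channels = c(2, 3, 4),
                                    inception_kernels = c(1, 3)), seed = 1)
  b <- build_network(network_config(c(32, 16, 24), enc_channels = c(2, 3, 4),
                                    inception_kernels = c(1, 3)), seed = 1)
  expect_identical(count_parameters(a), count_parameters(b))
})

test_that("network gradients match numerical differentiation through the loss", {
  shape <- c(8, 8, 8)
  cfg <- network_config(shape, enc_channels = c(2, 3, 4),
                        inception_kernels = c(1, 3))
  net <- build_network(cfg, seed = 3)
  m <- rand_vol(shape, 5); f <- rand_vol(shape, 6)
  w <- loss_weights(alpha = 1e-4, beta = 1e-3, ncc_window = 5)
  lossfun <- function(params) {
    fw <- lungwarp:::nn_forward(params, cfg, array(c(m, f), c(shape, 2L)))
    warped <- warp_trilinear(m, fw$field)
    total_loss(f, warped, fw$field, w)$total
  }
  st <- lungwarp:::pair_step(net$params, cfg, m, f, w, with_grads = TRUE)
  h <- 1e-5
  set.seed(9)
  for (blk in c("stem", "down3", "fuse2", "head")) {
    i <- sample(length(net$params[[blk]]$w), 1)
    pp <- net$params; pp[[blk]]$w[i] <- pp[[blk]]$w[i] + h
    pm <- net$params; pm[[blk]]$w[i] <- pm[[blk]]$w[i] - h
    num <- (lossfun(pp) - lossfun(pm)) / (2 * h)
    expect_equal(st$grads[[blk]]$w[i], num, tolerance = 1e-3)
  }
  i <- sample(length(net$params$incep1$branches[[2]]$w), 1)
  pp <- net$params; pp$incep1$branches[[2]]$w[i] <- pp$incep1$branches[[2]]$w[i] + h
  pm <- net$params; pm$incep1$branches[[2]]$w[i] <- pm$incep1$branches[[2]]$w[i] - h
  expect_equal(st$grads$incep1$branches[[2]]$w[i],
               (lossfun(pp) - lossfun(pm)) / (2 * h), tolerance = 1e-3)
})

test_that("one optimization step changes the parameters (gradients flow)", {
  shape <- c(8, 8, 8)
  cfg <- network_config(shape, enc_channels = c(2, 3, 4),
                        inception_kernels = c(1, 3))
  net <- build_network(cfg, seed = 7)
  st <- lungwarp:::pair_step(net$params, cfg, rand_vol(shape, 7),
                             rand_vol(shape, 8),
                             loss_weights(alpha = 1e-4, ncc_window = 5))
  upd <- lungwarp:::adam_step(net$params, st$grads,
                              lungwarp:::adam_init(net$params), 1e-3)
  for (blk in c("stem", "down1", "up3", "head"))
    expect_false(identical(upd$params[[blk]]$w, net$params[[blk]]$w))
})

test_that("invalid configurations are rejected", {
  expect_error(network_config(c(10, 8, 8)), "multiple of 8")
  expect_error(network_config(c(8, 8, 8), inception_kernels = c(2, 3)), "odd")
  expect_error(network_config(c(8, 8, 8), enc_channels = c(4, 8)), "3 positive")
})

test_that("checkpoints round trip through save/load", {
  cfg <- network_config(c(8, 8, 8), enc_channels = c(2, 3, 4),
                        inception_kernels = c(1, 3))
  net <- build_network(cfg, seed = 5)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path, extra = list(note = "x"))
  back <- load_checkpoint(path)
  expect_equal(back$params, net$params)
  expect_equal(back$cfg$enc_channels, cfg$enc_channels)
  expect_true(file.exists(paste0(path, ".yaml")))
  m <- rand_vol(c(8, 8, 8), 1); f <- rand_vol(c(8, 8, 8), 2)
  expect_identical(predict_field(net, m, f), predict_field(back, m, f))
})
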