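test_that("training reduces the mean total loss on the toy suite", {
  curve <- toy_curve()
  expect_lt(tail(curve$train_loss, 1), curve$train_loss[1])
  expect_true(all(is.finite(curve$train_loss)))
  expect_true(all(is.finite(curve$val_loss)))
})

test_that("training artifacts are written alongside the checkpoint", {
  ck <- toy_checkpoint()
  dir <- dirname(ck)
  expect_true(file.exists(file.path(dir, "loss_curve.csv")))
  expect_true(file.exists(file.path(dir, "best.rds")))
  expect_true(file.exists(file.path(dir, "last.rds")))
  expect_true(file.exists(file.path(dir, "run_train.json")))
})

test_that("training is bit-reproducible under a fixed seed", {
  man <- toy_suite()
  two <- lapply(1:2, function(k) {
    cfg <- train_config(learning_rate = 3e-3, epochs = 2,
                        loss_weights = toy_weights(), seed = 5,
                        checkpoint_dir = tempfile("ckdet"))
    attr(train(man[1:3, ], cfg, toy_net_cfg()), "curve")
  })
  expect_identical(two[[1]], two[[2]])
})

test_that("validation passes compute no gradients and mutate nothing", {
  cfg <- toy_net_cfg()
  net <- build_network(cfg, seed = 1)
  before <- net$params
  m <- rand_vol(c(16, 16, 16), 1); f <- rand_vol(c(16, 16, 16), 2)
  st <- lungwarp:::pair_step(net$params, cfg, m, f, toy_weights(),
                             with_grads = FALSE)
  expect_null(st$grads)
  expect_s3_class(st$report, "lw_loss_report")
  expect_identical(net$params, before)
})

test_that("missing manifest files fail before training starts", {
  man <- toy_suite()
  bad <- man[1:2, ]
  bad$moving[1] <- file.path(tempdir(), "does_not_exist.nii.gz")
  cfg <- train_config(epochs = 1, loss_weights = toy_weights(),
                      checkpoint_dir = tempfile())
  expect_error(train(bad, cfg, toy_net_cfg()), "missing files")
})

test_that("register_pair warps into [0,1] and orders similarity sensibly", {
  man <- toy_suite()
  ck <- toy_checkpoint()
  fixed1 <- read_volume(man$fixed[1])
  moving1 <- read_volume(man$moving[1])
  fixed2 <- read_volume(man$fixed[4])
  reg_self <- register_pair(ck, fixed1, fixed1)
  reg_match <- register_pair(ck, moving1, fixed1)
  reg_cross <- register_pair(ck, fixed2, fixed1)
  expect_gte(min(reg_match$warped$data), 0)
  expect_lte(max(reg_match$warped$data), 1)
  # a self-pair scores better than an unrelated pair from the same suite
  expect_lt(reg_self$report$l_sim, reg_cross$report$l_sim)
  expect_equal(dim(reg_match$field), c(16L, 16L, 16L, 3L))
})

test_that("register_pair enforces the checkpoint input shape", {
  ck <- toy_checkpoint()
  v <- lw_volume(rand_vol(c(8, 8, 8)))
  expect_error(register_pair(ck, v, v), "input shape")
})

test_that("train_config validates its invariants", {
  expect_error(train_config(learning_rate = 0), "> 0")
  expect_error(train_config(epochs = 0), ">= 1")
  expect_error(train_config(batch_size = 0), ">= 1")
})

test_that("minimizing the loss over the field alone improves similarity", {
  # no network: plain Adam on the displacement field of a translated pair
  d <- c(16, 16, 16)
  ph <- make_phantom(d, seed = 31)
  m <- ph$image$data
  shift <- array(0, c(d, 3)); shift[, , , 1] <- 1
  f <- as.array(warp_trilinear(m, shift))   # fixed = moving shifted by 1 voxel
  w <- loss_weights(alpha = 1e-4, beta = 1e-5, ncc_window = 7)
  field <- array(0, c(d, 3)); mm <- field; vv <- field
  sim0 <- sim_loss(f, m, w$ncc_window)
  for (it in 1:200) {
    warped <- warp_trilinear(m, field)
    gw <- -lungwarp:::ncc_grad_warped(f, warped, w$ncc_window, w$epsilon)
    g <- lungwarp:::warp_trilinear_bwd(m, field, gw)$gfield +
      w$beta * lungwarp:::jac_penalty_grad(field) +
      w$alpha * lungwarp:::grad_penalty_grad(field)
    mm <- 0.9 * mm + 0.1 * g
    vv <- 0.999 * vv + 0.001 * g^2
    field <- field - 0.05 * (mm / (1 - 0.9^it)) / (sqrt(vv / (1 - 0.999^it)) + 1e-8)
  }
  sim1 <- sim_loss(f, as.array(warp_trilinear(m, field)), w$ncc_window)
  expect_lt(sim1, sim0)
})
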