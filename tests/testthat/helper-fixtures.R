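# Session-cached toy suite and trained checkpoint, shared by the training and
# evaluation tests so the (seconds-scale) training run happens once.

.lw_test_cache <- new.env(parent = emptyenv())

toy_suite <- function() {
  if (is.null(.lw_test_cache$man)) {
    dir <- file.path(tempdir(), "lw_toy_suite")
    .lw_test_cache$man <- make_suite(dir, n_pairs = 6, shape = c(16, 16, 16),
                                     h_values = 0.05, n_landmarks = 15,
                                     seed = 11, val_fraction = 1 / 3)
  }
  .lw_test_cache$man
}

toy_net_cfg <- function() {
  network_config(c(16, 16, 16), enc_channels = c(2, 4, 8),
                 inception_kernels = c(1, 3))
}

toy_weights <- function() loss_weights(alpha = 1e-4, beta = 1e-5,
                                       ncc_window = 7)

toy_checkpoint <- function() {
  if (is.null(.lw_test_cache$ckpt)) {
    cfg <- train_config(learning_rate = 3e-3, epochs = 6,
                        loss_weights = toy_weights(), seed = 2,
                        checkpoint_dir = file.path(tempdir(), "lw_toy_ckpt"))
    ck <- train(toy_suite(), cfg, toy_net_cfg())
    .lw_test_cache$ckpt <- ck
    .lw_test_cache$curve <- attr(ck, "curve")
  }
  .lw_test_cache$ckpt
}

toy_curve <- function() {
  toy_checkpoint()
  .lw_test_cache$curve
}
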