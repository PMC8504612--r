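#' Training configuration
#'
#' Defaults mirror the reference training regime for full-resolution chest
#' CT: Adam, learning rate 1e-4, batch size 1, 20 epochs. Desk-scale runs on
#' small synthetic volumes typically raise the learning rate (see the
#' methods vignette).
#'
#' @param learning_rate Adam step size, > 0.
#' @param epochs number of passes over the training split, >= 1.
#' @param batch_size gradient-accumulation batch size, >= 1.
#' @param loss_weights an [loss_weights()] object.
#' @param seed integer seed controlling initialization and data order.
#' @param checkpoint_dir directory for checkpoints and the loss curve.
#' @return an object of class `lw_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 20L, batch_size = 1L,
                         loss_weights = lungwarp::loss_weights(),
                         seed = 1L, checkpoint_dir = tempfile("lw_ckpt_")) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  stopifnot(inherits(loss_weights, "lw_loss_weights"))
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, loss_weights = loss_weights,
                 seed = as.integer(seed), checkpoint_dir = checkpoint_dir),
            class = "lw_train_config")
}

# --- Adam over the nested parameter tree -----------------------------------

adam_init <- function(params) {
  zero <- function(x) {
    if (is.null(x)) NULL
    else if (is.list(x)) lapply(x, zero)
    else x * 0
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  upd <- function(p, g, m, v) {
    if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
    if (is.list(p)) {
      # gradient trees may list blocks in backward order: align by name
      if (!is.null(names(p)) && !is.null(names(g))) g <- g[names(p)]
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
    return(Map(grads_add, a, b))
  }
  a + b
}

grads_scale <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(lapply(a, grads_scale, s = s))
  a * s
}

# --- pair loading -----------------------------------------------------------

#' Extract (moving, fixed) training pairs from a manifest
#'
#' Accepts either the wide form written by [make_suite()] (columns `moving`,
#' `fixed`, optionally `split`) or the long form written by
#' [build_augmented_dataset()] (columns `split`, `pair_id`, `role`, `h`,
#' `replicate`, `path`), where each simulated replicate contributes one pair.
#'
#' @param manifest data frame or path to a manifest CSV.
#' @return data frame with columns `split`, `pair_id`, `moving`, `fixed`.
#' @export
pairs_from_manifest <- function(manifest) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (inherits(manifest, "lw_aug_manifest")) manifest <- manifest$records
  if (all(c("moving", "fixed") %in% names(manifest))) {
    out <- data.frame(split = manifest$split %||% rep("train", nrow(manifest)),
                      pair_id = manifest$pair_id %||% seq_len(nrow(manifest)),
                      moving = manifest$moving, fixed = manifest$fixed,
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (!all(c("pair_id", "role", "path") %in% names(manifest)))
    stop("manifest must have columns moving/fixed or pair_id/role/path",
         call. = FALSE)
  h_key <- manifest$h %||% rep(NA, nrow(manifest))
  r_key <- manifest$replicate %||% rep(NA, nrow(manifest))
  key <- paste(manifest$split %||% "train", manifest$pair_id,
               ifelse(is.na(h_key), "orig", h_key),
               ifelse(is.na(r_key), "0", r_key))
  rows <- split(manifest, key)
  out <- do.call(rbind, lapply(rows, function(r) {
    m <- r$path[r$role == "moving"]; f <- r$path[r$role == "fixed"]
    if (length(m) != 1L || length(f) != 1L)
      stop("manifest entry without exactly one moving and one fixed scan",
           call. = FALSE)
    data.frame(split = r$split[1] %||% "train",
               pair_id = as.character(r$pair_id[1]),
               moving = m, fixed = f, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

load_pair_arrays <- function(pairs) {
  missing <- !file.exists(pairs$moving) | !file.exists(pairs$fixed)
  if (any(missing))
    stop("manifest error: missing files:\n  ",
         paste(unique(c(pairs$moving[missing], pairs$fixed[missing])),
               collapse = "\n  "), call. = FALSE)
  lapply(seq_len(nrow(pairs)), function(i)
    list(m = vol_data(read_volume(pairs$moving[i])),
         f = vol_data(read_volume(pairs$fixed[i])),
         id = pairs$pair_id[i]))
}

# forward + loss (+ optional gradients) for one pair
pair_step <- function(params, cfg, m, f, w, with_grads = TRUE) {
  x <- array(c(m, f), c(dim(m), 2L))
  fw <- nn_forward(params, cfg, x)
  field <- fw$field
  warped <- .warp_trilinear_cpp(m, field)
  rep <- total_loss(f, warped, field, w)
  if (!is.finite(rep$total)) return(list(report = rep, grads = NULL))
  if (!with_grads) return(list(report = rep, grads = NULL))
  gwarped <- -ncc_grad_warped(f, warped, w$ncc_window, w$epsilon)
  gfield <- warp_trilinear_bwd(m, field, gwarped)$gfield
  if (w$beta > 0) gfield <- gfield + w$beta * jac_penalty_grad(field)
  if (w$alpha > 0) gfield <- gfield + w$alpha * grad_penalty_grad(field)
  list(report = rep, grads = nn_backward(params, cfg, fw$cache, gfield))
}

#' Train the registration network
#'
#' Unsupervised optimization: each step concatenates a (moving, fixed) pair,
#' predicts a displacement field, warps the moving image through the
#' differentiable trilinear layer and descends the composite loss
#' ([total_loss()]) with Adam. Per-epoch mean training and validation losses
#' are appended to `loss_curve.csv` in the checkpoint directory; the
#' checkpoint with the best validation total loss is retained (training loss
#' decides if the manifest has no validation split). The run is fully seeded:
#' initialization and shuffling derive from `cfg$seed`.
#'
#' @param manifest training pairs: anything [pairs_from_manifest()] accepts.
#' @param cfg an [train_config()].
#' @param net_cfg an [network_config()].
#' @return path of the best checkpoint, invisibly; the returned value carries
#'   the loss-curve data frame as attribute `"curve"`.
#' @export
train <- function(manifest, cfg, net_cfg) {
  stopifnot(inherits(cfg, "lw_train_config"), inherits(net_cfg, "lw_net_config"))
  pairs <- pairs_from_manifest(manifest)
  tr <- pairs[pairs$split == "train", , drop = FALSE]
  va <- pairs[pairs$split %in% c("val", "validation"), , drop = FALSE]
  if (!nrow(tr)) stop("manifest error: empty training split", call. = FALSE)
  train_data <- load_pair_arrays(tr)
  val_data <- if (nrow(va)) load_pair_arrays(va) else list()
  dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)

  net <- build_network(net_cfg, seed = cfg$seed)
  params <- net$params
  opt <- adam_init(params)
  w <- cfg$loss_weights
  curve <- data.frame()
  best <- Inf
  best_path <- file.path(cfg$checkpoint_dir, "best.rds")

  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      order <- sample.int(length(train_data))
      tot <- 0
      acc <- NULL
      nacc <- 0L
      for (ii in seq_along(order)) {
        d <- train_data[[order[ii]]]
        st <- pair_step(params, net_cfg, d$m, d$f, w, with_grads = TRUE)
        if (!is.finite(st$report$total))
          stop(sprintf("non-finite loss at epoch %d on pair '%s'", epoch, d$id),
               call. = FALSE)
        tot <- tot + st$report$total
        acc <- grads_add(acc, st$grads)
        nacc <- nacc + 1L
        if (nacc == cfg$batch_size || ii == length(order)) {
          upd <- adam_step(params, grads_scale(acc, 1 / nacc), opt,
                           cfg$learning_rate)
          params <- upd$params
          opt <- upd$state
          acc <- NULL
          nacc <- 0L
        }
      }
      train_loss <- tot / length(train_data)
      val_loss <- NA_real_
      if (length(val_data)) {
        vt <- vapply(val_data, function(d)
          pair_step(params, net_cfg, d$m, d$f, w, with_grads = FALSE)$report$total,
          numeric(1))
        val_loss <- mean(vt)
      }
      curve <- rbind(curve, data.frame(epoch = epoch, train_loss = train_loss,
                                       val_loss = val_loss))
      select_loss <- if (is.na(val_loss)) train_loss else val_loss
      if (select_loss < best) {
        best <- select_loss
        net$params <- params
        save_checkpoint(net, best_path,
                        extra = list(loss_weights = unclass(w), epoch = epoch,
                                     seed = cfg$seed))
      }
    }
  })
  net$params <- params
  save_checkpoint(net, file.path(cfg$checkpoint_dir, "last.rds"),
                  extra = list(loss_weights = unclass(w), epoch = cfg$epochs,
                               seed = cfg$seed))
  utils::write.csv(curve, file.path(cfg$checkpoint_dir, "loss_curve.csv"),
                   row.names = FALSE)
  cfg_plain <- unclass(cfg)
  cfg_plain$loss_weights <- unclass(w)
  write_run_record(cfg$checkpoint_dir, "train",
                   list(train = cfg_plain, network = unclass(net_cfg),
                        n_train = nrow(tr), n_val = nrow(va)))
  invisible(structure(best_path, curve = curve))
}

#' Register one pair with a trained network
#'
#' One forward pass predicts the displacement field; the moving image is
#' warped trilinearly and the loss report is computed with the weights the
#' checkpoint was trained with.
#'
#' @param checkpoint checkpoint path (from [train()]) or an `lw_network`.
#' @param moving,fixed preprocessed volumes on the network's input grid.
#' @return an `lw_registration`: list with `field` (X x Y x Z x 3 array),
#'   `warped` (volume like `moving`) and `report` (an `lw_loss_report`).
#' @export
register_pair <- function(checkpoint, moving, fixed) {
  net <- if (inherits(checkpoint, "lw_network")) checkpoint
         else load_checkpoint(checkpoint)
  extra <- attr(net, "extra") %||% list()
  m <- vol_data(moving); f <- vol_data(fixed)
  if (!all(dim(m) == dim(f))) stop("pair shape mismatch", call. = FALSE)
  if (!all(dim(m) == net$cfg$input_shape))
    stop(sprintf("volume shape (%s) does not match the checkpoint input shape (%s)",
                 paste(dim(m), collapse = "x"),
                 paste(net$cfg$input_shape, collapse = "x")), call. = FALSE)
  lw <- extra$loss_weights
  w <- if (is.null(lw)) loss_weights()
       else loss_weights(lw$alpha, lw$beta, lw$ncc_window, lw$epsilon)
  field <- predict_field(net, m, f)
  warped <- .warp_trilinear_cpp(m, field)
  structure(list(field = field,
                 warped = vol_like(warped, moving),
                 report = total_loss(f, warped, field, w)),
            class = "lw_registration")
}

#' @export
print.lw_registration <- function(x, ...) {
  cat("<lw_registration>\n  ")
  print(x$report)
  invisible(x)
}
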