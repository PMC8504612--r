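# Synthetic desk-scale fixtures: smooth blob phantoms deformed by a known
# random TPS, with matched masks and landmark sets, emulating intrapatient
# exhale/inhale chest CT pairs so the whole pipeline is testable offline.

#' Generate a smooth synthetic phantom with an ellipsoidal "lung field" mask
#'
#' A sum of random Gaussian blobs on a gentle intensity ramp, rescaled to
#' [0, 1], plus an ellipsoidal binary mask (semi-axes 38% of each dimension).
#' The default blob count and size range give dense small-scale structure
#' throughout the mask, mimicking the vascular/airway texture that windowed
#' correlation losses rely on in real lung CT; a texture-free phantom would
#' leave the similarity term without gradients. Deterministic per seed.
#'
#' @param shape integer length-3, each >= 8.
#' @param n_blobs number of Gaussian blobs (0 gives the ramp only).
#' @param seed integer seed.
#' @return list with `image` and `mask`, both [lw_volume()]s (spacing 1 mm).
#' @export
make_phantom <- function(shape, n_blobs = 40L, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("shape must be 3 integers >= 8", call. = FALSE)
  ctr <- (shape - 1) / 2
  semi <- 0.38 * shape
  g <- voxel_grid(shape)
  e <- ((g[, 1] - ctr[1]) / semi[1])^2 + ((g[, 2] - ctr[2]) / semi[2])^2 +
    ((g[, 3] - ctr[3]) / semi[3])^2
  mask <- array((e <= 1) * 1, shape)
  img <- with_seed(seed, {
    # gentle ramp keeps the volume non-constant even with no blobs
    acc <- 0.1 * (g[, 1] / max(shape[1] - 1, 1))
    if (n_blobs > 0) {
      centers <- sweep(matrix(stats::runif(3L * n_blobs, -0.85, 0.85),
                              ncol = 3), 2, semi, `*`)
      centers <- sweep(centers, 2, ctr, `+`)
      sigmas <- stats::runif(n_blobs, 0.03, 0.10) * min(shape)
      amps <- stats::runif(n_blobs, 0.3, 1)
      for (b in seq_len(n_blobs)) {
        r2 <- (g[, 1] - centers[b, 1])^2 + (g[, 2] - centers[b, 2])^2 +
          (g[, 3] - centers[b, 3])^2
        acc <- acc + amps[b] * exp(-r2 / (2 * sigmas[b]^2))
      }
    }
    array(acc, shape)
  })
  rng <- range(img)
  img <- (img - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  list(image = lw_volume(img), mask = lw_volume(mask, is_mask = TRUE))
}

#' Build one synthetic intrapatient pair with known ground truth
#'
#' The moving image is a phantom; the fixed image is the moving image warped
#' by a random TPS drawn on a 5^3 control lattice with perturbation
#' half-range `h` (normalized units; values up to 0.1 stay anatomically
#' plausible). Landmarks are placed at high-intensity-gradient sites inside
#' the fixed mask, and their moving-image correspondences are computed
#' analytically through the ground-truth transform, so registration accuracy
#' can be scored exactly.
#'
#' @param shape integer length-3, each >= 8.
#' @param h TPS perturbation half-range (normalized coordinates).
#' @param n_landmarks landmarks requested (reduced with a warning if too few
#'   high-gradient sites exist).
#' @param seed integer seed; the pair is bit-reproducible.
#' @return an `lw_synthetic_pair`: list with `moving`, `fixed`,
#'   `moving_mask`, `fixed_mask`, `gt_transform` (`lw_tps`), `gt_field`
#'   (X x Y x Z x 3 array on the fixed grid), `landmarks_fixed`,
#'   `landmarks_moving`, `h`, `seed`.
#' @export
make_pair <- function(shape, h = 0.05, n_landmarks = 50L, seed = 1L) {
  shape <- as.integer(shape)
  ph <- make_phantom(shape, seed = seed)
  gt <- random_grid_tps(5L, h, seed = seed + 1L)
  fixed <- warp_volume_tps(ph$image, gt)
  fixed_mask <- warp_volume_tps(ph$mask, gt)
  gt_field <- tps_displacement_field(gt, shape)

  # landmark sites: strong local gradient, inside the fixed mask, away from
  # the border, and mapping inside the moving grid
  gx <- fdiff(fixed$data, 1); gy <- fdiff(fixed$data, 2); gz <- fdiff(fixed$data, 3)
  gmag <- sqrt(gx^2 + gy^2 + gz^2)
  g <- voxel_grid(shape)
  interior <- g[, 1] >= 2 & g[, 1] <= shape[1] - 3 &
    g[, 2] >= 2 & g[, 2] <= shape[2] - 3 &
    g[, 3] >= 2 & g[, 3] <= shape[3] - 3
  inmask <- as.vector(fixed_mask$data) > 0
  thr <- stats::quantile(gmag[inmask], 0.7)
  cand <- which(interior & inmask & as.vector(gmag) >= thr)
  if (length(cand)) {
    xf_all <- g[cand, , drop = FALSE]
    xm_all <- xf_all + matrix(gt_field[cbind(
      rep(xf_all[, 1] + 1, 3), rep(xf_all[, 2] + 1, 3), rep(xf_all[, 3] + 1, 3),
      rep(1:3, each = nrow(xf_all)))], ncol = 3)
    ok <- xm_all[, 1] >= 0 & xm_all[, 1] <= shape[1] - 1 &
      xm_all[, 2] >= 0 & xm_all[, 2] <= shape[2] - 1 &
      xm_all[, 3] >= 0 & xm_all[, 3] <= shape[3] - 1
    cand <- cand[ok]
    xf_all <- xf_all[ok, , drop = FALSE]
    xm_all <- xm_all[ok, , drop = FALSE]
  }
  if (length(cand) < n_landmarks) {
    warning(sprintf("only %d valid landmark sites (requested %d)",
                    length(cand), n_landmarks), call. = FALSE)
    keep <- seq_along(cand)
  } else {
    keep <- with_seed(seed + 2L, sample.int(length(cand), n_landmarks))
  }
  structure(list(
    moving = ph$image, fixed = fixed,
    moving_mask = ph$mask, fixed_mask = fixed_mask,
    gt_transform = gt, gt_field = gt_field,
    landmarks_fixed = lw_landmarks(xf_all[keep, , drop = FALSE], "fixed"),
    landmarks_moving = lw_landmarks(xm_all[keep, , drop = FALSE], "moving"),
    h = h, seed = as.integer(seed)
  ), class = "lw_synthetic_pair")
}

#' @export
print.lw_synthetic_pair <- function(x, ...) {
  cat(sprintf("<lw_synthetic_pair> %s voxels, h = %g, %d landmarks, seed %d\n",
              paste(dim(x$moving), collapse = "x"), x$h,
              nrow(x$landmarks_fixed$points), x$seed))
  invisible(x)
}

#' Write a suite of synthetic pairs to disk
#'
#' Generates `n_pairs` synthetic pairs (cycling through `h_values`), writes
#' images, masks, ground-truth fields (NIfTI), landmark files (1-based on
#' disk) and a manifest CSV compatible with [train()] and
#' [evaluate_testset()]. Per-pair seeds derive from the base seed
#' (`seed + index`), so any single pair can be regenerated in isolation.
#'
#' @param out_dir output directory (created if needed).
#' @param n_pairs number of pairs, >= 1.
#' @param shape volume shape.
#' @param h_values TPS perturbation half-ranges to cycle through.
#' @param n_landmarks landmarks per pair.
#' @param seed base seed.
#' @param val_fraction fraction of pairs assigned to the validation split.
#' @return the manifest data frame, invisibly; also written as
#'   `manifest.csv` in `out_dir`.
#' @export
make_suite <- function(out_dir, n_pairs = 20L, shape = c(32L, 32L, 32L),
                       h_values = c(0.02, 0.05), n_landmarks = 50L,
                       seed = 7L, val_fraction = 0.2) {
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_val <- floor(val_fraction * n_pairs)
  rows <- lapply(seq_len(n_pairs), function(i) {
    h <- h_values[(i - 1L) %% length(h_values) + 1L]
    pr <- make_pair(shape, h = h, n_landmarks = n_landmarks, seed = seed + i)
    pid <- sprintf("p%03d", i)
    paths <- list(
      moving = file.path(out_dir, paste0(pid, "_moving.nii.gz")),
      fixed = file.path(out_dir, paste0(pid, "_fixed.nii.gz")),
      moving_mask = file.path(out_dir, paste0(pid, "_moving_mask.nii.gz")),
      fixed_mask = file.path(out_dir, paste0(pid, "_fixed_mask.nii.gz")),
      gt_field = file.path(out_dir, paste0(pid, "_gt_field.nii.gz")),
      landmarks_fixed = file.path(out_dir, paste0(pid, "_landmarks_fixed.txt")),
      landmarks_moving = file.path(out_dir, paste0(pid, "_landmarks_moving.txt"))
    )
    write_volume(pr$moving, paths$moving)
    write_volume(pr$fixed, paths$fixed)
    write_volume(pr$moving_mask, paths$moving_mask)
    write_volume(pr$fixed_mask, paths$fixed_mask)
    write_field(pr$gt_field, paths$gt_field)
    write_landmarks(pr$landmarks_fixed, paths$landmarks_fixed)
    write_landmarks(pr$landmarks_moving, paths$landmarks_moving)
    data.frame(split = if (i > n_pairs - n_val) "val" else "train",
               pair_id = pid, h = h, seed = seed + i,
               moving = paths$moving, fixed = paths$fixed,
               moving_mask = paths$moving_mask, fixed_mask = paths$fixed_mask,
               landmarks_fixed = paths$landmarks_fixed,
               landmarks_moving = paths$landmarks_moving,
               gt_field = paths$gt_field,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  write_run_record(out_dir, "fixtures",
                   list(n_pairs = n_pairs, shape = shape, h_values = h_values,
                        n_landmarks = n_landmarks, seed = seed,
                        val_fraction = val_fraction))
  invisible(manifest)
}
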