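#' Landmark target registration error (TRE)
#'
#' Maps each fixed-image landmark `x` through the predicted transform
#' `phi(x) = x + s(x)` (the field interpolated trilinearly at the generally
#' non-integer landmark position), takes the residual to the corresponding
#' moving-image landmark, converts it to mm per axis with the fixed image's
#' spacing, and returns the mean and population standard deviation of the
#' Euclidean residuals. TRE is directional: it evaluates the field that maps
#' fixed-grid positions into the moving image's space, the same convention
#' [warp_trilinear()] uses.
#'
#' @param fixed_lms,moving_lms [lw_landmarks()] with equal point counts;
#'   `fixed_lms` lies on the field's grid.
#' @param field X x Y x Z x 3 displacement array (voxel units) or `NULL` for
#'   the unregistered (zero-field) baseline.
#' @param spacing mm per voxel of the fixed grid.
#' @return named numeric: `mean` and `sd`, both in mm.
#' @export
tre <- function(fixed_lms, moving_lms, field = NULL, spacing = c(1, 1, 1)) {
  stopifnot(inherits(fixed_lms, "lw_landmarks"),
            inherits(moving_lms, "lw_landmarks"))
  xf <- fixed_lms$points
  xm <- moving_lms$points
  if (nrow(xf) != nrow(xm))
    stop("landmark sets must have equal point counts", call. = FALSE)
  if (!is.null(field)) {
    field <- as_field(field)
    check_landmarks_in_grid(fixed_lms, dim(field)[1:3])
    s_at <- vapply(1:3, function(c)
      .sample_volume_cpp(field[, , , c], xf, 0L), numeric(nrow(xf)))
    mapped <- xf + s_at
  } else {
    mapped <- xf
  }
  resid <- sweep(mapped - xm, 2, as.numeric(spacing), `*`)
  d <- sqrt(rowSums(resid^2))
  c(mean = mean(d), sd = sqrt(mean((d - mean(d))^2)))
}

#' Dice overlap of two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`. Defined as 1 when both masks are empty (with a
#' message, since that normally signals an upstream problem).
#'
#' @param warped_mask,fixed_mask binary volumes or arrays of equal shape.
#' @return scalar in [0, 1].
#' @export
dice <- function(warped_mask, fixed_mask) {
  a <- vol_data(warped_mask); b <- vol_data(fixed_mask)
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("dice expects binary masks", call. = FALSE)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    message("dice of two empty masks: defined as 1")
    return(1)
  }
  2 * sum(a * b) / (sa + sb)
}

#' Count folding voxels of a displacement field
#'
#' Number of voxels where the Jacobian determinant of the full map
#' `phi = id + s` is <= 0 (see [jacobian_determinant_map()]).
#'
#' @inheritParams jacobian_determinant_map
#' @return integer count, >= 0.
#' @export
folding_count <- function(field) {
  sum(jacobian_determinant_map(field) <= 0)
}

#' Evaluate a trained model over a test set
#'
#' For each pair: registers moving to fixed, computes the initial
#' (zero-field) and post-registration TRE from the landmark files, the Dice
#' overlap of the nearest-neighbour-warped moving mask against the fixed
#' mask (and its unregistered baseline), and the folding-voxel count.
#' Unreadable pairs are skipped with a warning and excluded from the summary.
#' A final `summary` row holds the column means.
#'
#' @param checkpoint checkpoint path or `lw_network`.
#' @param pairs data frame with columns `pair_id`, `moving`, `fixed`,
#'   `moving_mask`, `fixed_mask`, `landmarks_fixed`, `landmarks_moving`
#'   (file paths), e.g. the manifest written by [make_suite()].
#' @param out_csv optional path; when given the table is written as CSV.
#' @return data frame of per-pair records plus the summary row.
#' @export
evaluate_testset <- function(checkpoint, pairs, out_csv = NULL) {
  if (is.character(pairs)) pairs <- utils::read.csv(pairs, stringsAsFactors = FALSE)
  need <- c("pair_id", "moving", "fixed", "moving_mask", "fixed_mask",
            "landmarks_fixed", "landmarks_moving")
  if (!all(need %in% names(pairs)))
    stop("pairs table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  net <- if (inherits(checkpoint, "lw_network")) checkpoint
         else load_checkpoint(checkpoint)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    rec <- tryCatch({
      moving <- read_volume(pairs$moving[i])
      fixed <- read_volume(pairs$fixed[i])
      mmask <- read_volume(pairs$moving_mask[i], kind = "mask")
      fmask <- read_volume(pairs$fixed_mask[i], kind = "mask")
      lf <- read_landmarks(pairs$landmarks_fixed[i], frame = "fixed")
      lm <- read_landmarks(pairs$landmarks_moving[i], frame = "moving")
      reg <- register_pair(net, moving, fixed)
      t0 <- tre(lf, lm, field = NULL, spacing = fixed$spacing)
      t1 <- tre(lf, lm, field = reg$field, spacing = fixed$spacing)
      data.frame(
        pair_id = as.character(pairs$pair_id[i]),
        initial_tre_mean_mm = t0[["mean"]],
        tre_mean_mm = t1[["mean"]],
        tre_std_mm = t1[["sd"]],
        initial_dice = dice(mmask, fmask),
        dice = dice(warp_nearest(mmask, reg$field), fmask),
        folding_count = reg$report$folding_count,
        stringsAsFactors = FALSE
      )
    }, error = function(e) {
      warning(sprintf("skipping pair '%s': %s", pairs$pair_id[i],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(out)) {
    num <- vapply(out[-1], mean, numeric(1))
    out <- rbind(out, c(list(pair_id = "summary"), as.list(num)))
  }
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
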