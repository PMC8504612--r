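#' TPS-based data augmentation of intrapatient pairs
#'
#' For every original pair and every combination of perturbation half-range
#' `h` and replicate index, draws one random TPS on a `grid_n^3` control
#' lattice and warps BOTH members of the pair through the same transform, so
#' each simulated pair remains intrapatient-like. Simulated scans are written
#' as NIfTI; the returned manifest records the originals plus every simulated
#' scan, so the total count is
#' `2 * n_pairs * (1 + per_h_replicates * length(h_values))` — the reference
#' configuration (25 replicates at each of h = 0.02, 0.05, 0.08, 0.1) turns
#' 30 pairs into 6060 scans and 6 pairs into 1212.
#'
#' Each record's TPS draw uses seed `seed + record_index`, so any single
#' simulated scan is reproducible in isolation.
#'
#' @param pairs data frame with columns `pair_id`, `moving`, `fixed` (paths
#'   to volumes readable by [read_volume()]).
#' @param out_dir directory for the simulated scans, the manifest CSV and the
#'   YAML configuration record.
#' @param per_h_replicates simulated pairs per (original pair, h), >= 0.
#' @param h_values TPS perturbation half-ranges (normalized coordinates).
#' @param grid_n control points per axis (default 5, N = 125).
#' @param seed base seed.
#' @param split split label recorded for every scan (default `"train"`).
#' @return an `lw_aug_manifest`: list with `records` (one row per scan:
#'   `split`, `pair_id`, `role`, `h`, `replicate`, `seed`, `path`) and
#'   `counts` (`originals`, `simulated`, `total`).
#' @export
build_augmented_dataset <- function(pairs, out_dir, per_h_replicates = 25L,
                                    h_values = c(0.02, 0.05, 0.08, 0.1),
                                    grid_n = 5L, seed = 1L, split = "train") {
  if (is.character(pairs)) pairs <- utils::read.csv(pairs, stringsAsFactors = FALSE)
  if (!nrow(pairs)) stop("pairs must be nonempty", call. = FALSE)
  if (!all(c("pair_id", "moving", "fixed") %in% names(pairs)))
    stop("pairs needs columns pair_id, moving, fixed", call. = FALSE)
  per_h_replicates <- as.integer(per_h_replicates)
  if (per_h_replicates < 0L) stop("per_h_replicates must be >= 0", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  records <- list()
  add <- function(...) records[[length(records) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  ridx <- 0L
  for (i in seq_len(nrow(pairs))) {
    pid <- as.character(pairs$pair_id[i])
    moving <- read_volume(pairs$moving[i])
    fixed <- read_volume(pairs$fixed[i])
    add(split = split, pair_id = pid, role = "moving", h = NA_real_,
        replicate = NA_integer_, seed = NA_integer_, path = pairs$moving[i])
    add(split = split, pair_id = pid, role = "fixed", h = NA_real_,
        replicate = NA_integer_, seed = NA_integer_, path = pairs$fixed[i])
    for (h in h_values) {
      for (r in seq_len(per_h_replicates)) {
        ridx <- ridx + 1L
        rec_seed <- as.integer(seed) + ridx
        t <- random_grid_tps(grid_n, h, seed = rec_seed)
        wp <- warp_pair_tps(moving, fixed, t)
        wm <- wp$moving
        wf <- wp$fixed
        base <- sprintf("%s_h%0.2f_r%02d", pid, h, r)
        pm <- file.path(out_dir, paste0(base, "_moving.nii.gz"))
        pf <- file.path(out_dir, paste0(base, "_fixed.nii.gz"))
        write_volume(wm, pm)
        write_volume(wf, pf)
        add(split = split, pair_id = pid, role = "moving", h = h,
            replicate = r, seed = rec_seed, path = pm)
        add(split = split, pair_id = pid, role = "fixed", h = h,
            replicate = r, seed = rec_seed, path = pf)
      }
    }
  }
  records <- do.call(rbind, records)
  counts <- list(originals = 2L * nrow(pairs),
                 simulated = nrow(records) - 2L * nrow(pairs),
                 total = nrow(records))
  utils::write.csv(records, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(grid_n = as.integer(grid_n), h_values = h_values,
                        per_h_replicates = per_h_replicates,
                        seed = as.integer(seed)),
                   file.path(out_dir, "augment_config.yaml"))
  structure(list(records = records, counts = counts),
            class = "lw_aug_manifest")
}

#' @export
print.lw_aug_manifest <- function(x, ...) {
  cat(sprintf("<lw_aug_manifest> %d scans (%d original + %d simulated)\n",
              x$counts$total, x$counts$originals, x$counts$simulated))
  invisible(x)
}
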