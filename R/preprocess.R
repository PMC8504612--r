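#' Rescale intensities linearly to [0, 1]
#'
#' @param v an [lw_volume()] (not a mask) with non-constant intensities.
#' @return a volume with `min = 0`, `max = 1`.
#' @export
normalize_intensity <- function(v) {
  stopifnot(inherits(v, "lw_volume"))
  if (v$is_mask) stop("refusing to normalize a mask volume", call. = FALSE)
  r <- range(v$data)
  if (r[2] <= r[1])
    stop("degenerate input: constant volume cannot be normalized", call. = FALSE)
  vol_like((v$data - r[1]) / (r[2] - r[1]), v)
}

#' Crop to a mask bounding box and resample to a target shape
#'
#' Extracts the bounding box of the nonzero mask voxels (plus `margin` voxels
#' on every side, clamped to the grid) and resamples the cropped block to
#' `target_shape` — trilinearly for images, nearest-neighbour for masks.
#' Spacing is rescaled so the physical extent of the block is preserved
#' (new spacing = old spacing x cropped dim / target dim); the origin moves
#' to the cropped corner.
#'
#' @param v volume to crop (image or mask).
#' @param mask binary [lw_volume()] defining the bounding box (commonly the
#'   union of the pair's lung masks, see [mask_union()]).
#' @param target_shape integer length-3, every component >= 2.
#' @param margin voxels of padding around the bounding box (default 2).
#' @return the cropped, resampled [lw_volume()].
#' @export
crop_resample <- function(v, mask, target_shape, margin = 2L) {
  stopifnot(inherits(v, "lw_volume"), inherits(mask, "lw_volume"))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 2L))
    stop("target_shape must be 3 integers >= 2", call. = FALSE)
  if (!any(mask$data > 0))
    stop("degenerate input: empty mask", call. = FALSE)
  if (!all(dim(mask) == dim(v)))
    stop("mask and volume shapes differ", call. = FALSE)
  nz <- which(mask$data > 0, arr.ind = TRUE)
  lo <- pmax(apply(nz, 2, min) - margin, 1L)
  hi <- pmin(apply(nz, 2, max) + margin, dim(v))
  cropped <- v$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  nc <- dim(cropped)
  # sample positions: endpoints map to endpoints, identity when shapes match
  coords <- lapply(1:3, function(a)
    if (target_shape[a] == 1L) (nc[a] - 1) / 2
    else seq(0, nc[a] - 1, length.out = target_shape[a]))
  pts <- as.matrix(expand.grid(coords[[1]], coords[[2]], coords[[3]]))
  vals <- .sample_volume_cpp(cropped, pts, if (v$is_mask) 1L else 0L)
  out <- array(vals, target_shape)
  if (v$is_mask) out <- (out > 0.5) * 1
  lw_volume(out,
            spacing = v$spacing * nc / target_shape,
            origin = v$origin + (lo - 1) * v$spacing,
            is_mask = v$is_mask)
}

#' Union of two binary masks
#' @param a,b mask volumes on the same grid.
#' @return a mask volume, nonzero where either input is.
#' @export
mask_union <- function(a, b) {
  stopifnot(inherits(a, "lw_volume"), inherits(b, "lw_volume"),
            all(dim(a) == dim(b)))
  vol_like((a$data > 0 | b$data > 0) * 1, a, is_mask = TRUE)
}

#' Preprocess an intrapatient pair onto a common grid
#'
#' Normalizes both images, crops both to the union of the two lung masks
#' (so the pair shares one grid) and resamples everything to `target_shape`.
#'
#' @param moving,fixed image volumes.
#' @param moving_mask,fixed_mask binary lung masks on the same grids.
#' @param target_shape network input shape (each dimension >= 2).
#' @param margin crop margin in voxels.
#' @return list with `moving`, `fixed`, `moving_mask`, `fixed_mask`.
#' @export
preprocess_pair <- function(moving, fixed, moving_mask, fixed_mask,
                            target_shape, margin = 2L) {
  u <- mask_union(moving_mask, fixed_mask)
  list(
    moving = crop_resample(normalize_intensity(moving), u, target_shape, margin),
    fixed = crop_resample(normalize_intensity(fixed), u, target_shape, margin),
    moving_mask = crop_resample(moving_mask, u, target_shape, margin),
    fixed_mask = crop_resample(fixed_mask, u, target_shape, margin)
  )
}
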