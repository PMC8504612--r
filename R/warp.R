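#' Warp a volume by a dense displacement field (spatial transformation layer)
#'
#' `warp_trilinear()` computes `out(p) = moving(p + s(p))` by trilinear
#' interpolation of the eight neighbouring voxels; sample coordinates clamp
#' to the volume border. The operation is differentiable in both the volume
#' and the field (the internal backward pass is what training uses), so the
#' warped output can sit inside a loss that is minimized by gradient descent.
#' `warp_nearest()` is the nearest-neighbour variant used for binary masks
#' (fractions of exactly 0.5 round half-up per axis, so mask warps are
#' bit-reproducible).
#'
#' @param moving an [lw_volume()] or 3D array on the fixed grid.
#' @param field X x Y x Z x 3 displacement array, voxel units, shape matching
#'   `moving` plus the trailing component axis.
#' @return the warped volume (same class as the input).
#' @examples
#' v <- array(runif(6^3), c(6, 6, 6))
#' s <- array(0, c(6, 6, 6, 3))
#' identical(warp_trilinear(v, s), v)
#' @export
warp_trilinear <- function(moving, field) {
  arr <- vol_data(moving)
  field <- as_field(field)
  if (!all(dim(field)[1:3] == dim(arr)))
    stop("field shape does not match the volume", call. = FALSE)
  out <- .warp_trilinear_cpp(arr, field)
  vol_like(out, moving)
}

#' @rdname warp_trilinear
#' @param mask a binary mask volume.
#' @export
warp_nearest <- function(mask, field) {
  arr <- vol_data(mask)
  if (inherits(mask, "lw_volume") && !mask$is_mask)
    stop("warp_nearest expects a mask volume", call. = FALSE)
  if (!all(arr %in% c(0, 1)))
    stop("warp_nearest expects a binary volume", call. = FALSE)
  field <- as_field(field)
  if (!all(dim(field)[1:3] == dim(arr)))
    stop("field shape does not match the volume", call. = FALSE)
  out <- .warp_nearest_cpp(arr, field)
  vol_like(out, mask, is_mask = TRUE)
}

# backward pass of the trilinear warp; internal, used by training and tested
# against numerical differentiation
warp_trilinear_bwd <- function(moving, field, gout) {
  .warp_trilinear_bwd_cpp(vol_data(moving), as_field(field), gout)
}
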