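#' Fit a 3D thin-plate-spline transform through control-point pairs
#'
#' Solves the classical TPS interpolation problem per output axis: the
#' transform `f` is an affine part plus a sum of radial kernels
#' `U(r) = r^2 log(r)` (natural log; `U(0) = 0`) centred at the source
#' control points, constrained to interpolate every pair
#' (`f(control_src[i, ]) = control_dst[i, ]`) with vanishing moments of the
#' radial weights (`t(P) %*% w = 0`). The `(N+4) x (N+4)` bordered system is
#' solved densely; a `1e-10` diagonal regularization of the kernel block is
#' applied only if the plain solve reports (near-)singularity, and its use is
#' messaged.
#'
#' @param control_src N x 3 matrix of pairwise-distinct source points
#'   (normalized coordinates in `[0,1]^3`), N >= 5.
#' @param control_dst N x 3 matrix of target points.
#' @return an object of class `lw_tps` with elements `control_src`,
#'   `control_dst`, `weights` (N x 3) and `affine` (4 x 3: intercept then
#'   x, y, z coefficients per output axis).
#' @examples
#' src <- as.matrix(expand.grid(c(0, .5, 1), c(0, .5, 1), c(0, .5, 1)))
#' t0 <- fit_tps(src, src + 0.1)  # pure translation
#' max(abs(evaluate_tps(t0, src) - (src + 0.1)))
#' @export
fit_tps <- function(control_src, control_dst) {
  src <- as.matrix(control_src); dst <- as.matrix(control_dst)
  n <- nrow(src)
  if (n < 5L) stop("need at least 5 control points", call. = FALSE)
  if (!all(dim(src) == c(n, 3L)) || !all(dim(dst) == c(n, 3L)))
    stop("control points must be N x 3 matrices of equal N", call. = FALSE)
  d2 <- pairwise_sqdist(src, src)
  if (any(d2[upper.tri(d2)] < 1e-24))
    stop("duplicate control points make the TPS system singular", call. = FALSE)
  K <- tps_kernel_from_sq(d2)
  P <- cbind(1, src)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  V <- rbind(dst, matrix(0, 4, 3))
  sol <- tryCatch({
    if (rcond(M) < 1e-14) stop("near-singular")
    solve(M, V)
  }, error = function(e) {
    kappa_est <- tryCatch(1 / rcond(M), error = function(e2) Inf)
    message(sprintf(
      "TPS system near-singular (condition estimate %.3g); regularizing kernel diagonal by 1e-10",
      kappa_est))
    M2 <- M
    diag(M2)[1:n] <- diag(M2)[1:n] + 1e-10
    tryCatch(solve(M2, V), error = function(e3)
      stop(sprintf(
        "singular TPS system (coplanar or duplicate control points; condition estimate %.3g)",
        kappa_est), call. = FALSE))
  })
  structure(list(control_src = src, control_dst = dst,
                 weights = sol[1:n, , drop = FALSE],
                 affine = sol[(n + 1):(n + 4), , drop = FALSE]),
            class = "lw_tps")
}

#' @export
print.lw_tps <- function(x, ...) {
  cat(sprintf("<lw_tps> %d control points, max |weight| %.3g\n",
              nrow(x$control_src), max(abs(x$weights))))
  invisible(x)
}

# squared Euclidean distances between rows of a (m x 3) and b (n x 3)
pairwise_sqdist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

# U(r) = r^2 log r evaluated from squared distances; U(0) = 0 (the limit)
tps_kernel_from_sq <- function(d2) {
  u <- 0.5 * d2 * log(d2)  # r^2 log r = d2 * log(sqrt(d2))
  u[d2 == 0] <- 0
  u
}

#' Evaluate a TPS transform at points
#'
#' @param t an `lw_tps` from [fit_tps()].
#' @param points M x 3 matrix in normalized coordinates.
#' @return M x 3 matrix of mapped points.
#' @export
evaluate_tps <- function(t, points) {
  stopifnot(inherits(t, "lw_tps"))
  pts <- as.matrix(points)
  if (ncol(pts) != 3L) stop("points must be M x 3", call. = FALSE)
  U <- tps_kernel_from_sq(pairwise_sqdist(pts, t$control_src))
  cbind(1, pts) %*% t$affine + U %*% t$weights
}

#' Draw a random TPS deformation on a regular control lattice
#'
#' Source control points are a `grid_n^3` lattice spanning the unit cube;
#' each target point is the source point plus an i.i.d. uniform(-h, h)
#' perturbation per coordinate. `h` is in normalized coordinates, so
#' `h = 0.1` displaces control points by up to 10% of each axis extent;
#' values in 0.02-0.1 keep the simulated deformations anatomically plausible
#' (larger h risks overstretching and folding).
#'
#' @param grid_n control points per axis (default 5, i.e. N = 125).
#' @param h perturbation half-range in normalized coordinates, >= 0.
#' @param seed integer seed; the draw is fully reproducible.
#' @return an `lw_tps`.
#' @export
random_grid_tps <- function(grid_n = 5L, h = 0.05, seed = 1L) {
  grid_n <- as.integer(grid_n)
  if (grid_n < 2L) stop("grid_n must be >= 2", call. = FALSE)
  if (h < 0) stop("h must be >= 0", call. = FALSE)
  ax <- seq(0, 1, length.out = grid_n)
  src <- as.matrix(expand.grid(ax, ax, ax))
  dimnames(src) <- NULL
  dst <- src + with_seed(seed, matrix(stats::runif(3 * nrow(src), -h, h),
                                      ncol = 3))
  fit_tps(src, dst)
}

#' Warp a volume through a TPS transform
#'
#' Backward mapping: each output voxel's normalized coordinate is pushed
#' through the transform and the input volume is sampled there (trilinear
#' for images, nearest-neighbour for masks; out-of-range samples clamp to
#' the border). With the identity transform the output equals the input.
#'
#' @param v an [lw_volume()] or 3D array.
#' @param t an `lw_tps`.
#' @return the warped volume (same class as `v`).
#' @export
warp_volume_tps <- function(v, t) {
  arr <- vol_data(v)
  d <- dim(arr)
  pts <- voxel_grid(d)
  npts <- sweep(pts, 2, pmax(d - 1, 1), `/`)
  mapped <- evaluate_tps(t, npts)
  src <- sweep(mapped, 2, pmax(d - 1, 1), `*`)
  is_mask <- inherits(v, "lw_volume") && v$is_mask
  vals <- .sample_volume_cpp(arr, src, if (is_mask) 1L else 0L)
  out <- array(vals, d)
  if (is_mask) out <- (out > 0.5) * 1
  vol_like(out, v)
}

# warp both members of an equally-shaped pair through one TPS draw,
# evaluating the coordinate mapping only once
warp_pair_tps <- function(moving, fixed, t) {
  am <- vol_data(moving); af <- vol_data(fixed)
  stopifnot(all(dim(am) == dim(af)))
  d <- dim(am)
  pts <- voxel_grid(d)
  src <- sweep(evaluate_tps(t, sweep(pts, 2, pmax(d - 1, 1), `/`)),
               2, pmax(d - 1, 1), `*`)
  list(moving = vol_like(array(.sample_volume_cpp(am, src, 0L), d), moving),
       fixed = vol_like(array(.sample_volume_cpp(af, src, 0L), d), fixed))
}

#' Dense displacement field induced by a TPS transform
#'
#' Evaluates the transform analytically at every voxel of `shape` and
#' returns `s(p) = f(p) - p` in voxel units on that grid — the ground-truth
#' field for synthetic pairs built with [warp_volume_tps()].
#'
#' @param t an `lw_tps`.
#' @param shape integer length-3 grid shape.
#' @return X x Y x Z x 3 displacement array (voxel units).
#' @export
tps_displacement_field <- function(t, shape) {
  shape <- as.integer(shape)
  pts <- voxel_grid(shape)
  npts <- sweep(pts, 2, pmax(shape - 1, 1), `/`)
  mapped <- sweep(evaluate_tps(t, npts), 2, pmax(shape - 1, 1), `*`)
  array(mapped - pts, c(shape, 3L))
}
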