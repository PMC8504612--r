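#' Loss weights and windowing for the composite registration objective
#'
#' @param alpha weight of the first-derivative smoothness penalty.
#' @param beta weight of the Jacobian folding penalty (full-resolution
#'   training regimes typically explore 1e-5 to 1e-2).
#' @param ncc_window odd window edge length (voxels) for the local NCC;
#'   11 at full CT resolution, smaller for desk-scale volumes.
#' @param epsilon variance-stabilizing constant added to the NCC denominator.
#' @return an object of class `lw_loss_weights`.
#' @export
loss_weights <- function(alpha = 1, beta = 1e-5, ncc_window = 11L,
                         epsilon = 1e-5) {
  ncc_window <- as.integer(ncc_window)
  if (ncc_window < 3L || ncc_window %% 2L == 0L)
    stop("ncc_window must be odd and >= 3", call. = FALSE)
  if (alpha < 0 || beta < 0 || epsilon < 0)
    stop("alpha, beta and epsilon must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, ncc_window = ncc_window,
                 epsilon = epsilon),
            class = "lw_loss_weights")
}

# windowed sums shared by the NCC value and its gradient
ncc_terms <- function(f, g, window, epsilon) {
  r <- (window - 1L) %/% 2L
  n <- box_count3(dim(f), r)
  muf <- .box_sum3_cpp(f, r) / n
  mug <- .box_sum3_cpp(g, r) / n
  A <- .box_sum3_cpp(f * g, r) - n * muf * mug
  B <- pmax(.box_sum3_cpp(f * f, r) - n * muf^2, 0)
  C <- pmax(.box_sum3_cpp(g * g, r) - n * mug^2, 0)
  list(A = A, B = B, C = C, den = B * C + epsilon, muf = muf, mug = mug, r = r)
}

#' Local squared normalized cross-correlation
#'
#' For every voxel, the squared covariance of the two images over the
#' surrounding window (truncated at the border) divided by the product of
#' the two windowed sums of squared deviations (plus `epsilon`); the
#' returned value is the mean over all voxels and lies in [0, 1]. Identical
#' or positively affinely related images score (near) 1.
#'
#' @param fixed,warped volumes or 3D arrays of equal shape.
#' @param window odd window edge length in voxels.
#' @param epsilon denominator stabilizer.
#' @return scalar in [0, 1].
#' @export
local_ncc <- function(fixed, warped, window = 11L, epsilon = 1e-5) {
  f <- vol_data(fixed); g <- vol_data(warped)
  if (!all(dim(f) == dim(g))) stop("shape mismatch", call. = FALSE)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3", call. = FALSE)
  tm <- ncc_terms(f, g, window, epsilon)
  mean(tm$A^2 / tm$den)
}

#' Similarity loss: one minus the local squared NCC
#' @inheritParams local_ncc
#' @return scalar in [0, 1]; 0 for identical (non-constant) images.
#' @export
sim_loss <- function(fixed, warped, window = 11L, epsilon = 1e-5) {
  1 - local_ncc(fixed, warped, window, epsilon)
}

# d(local_ncc)/d(warped): box-filter form of the windowed-correlation
# gradient; verified against numerical differentiation in the tests
ncc_grad_warped <- function(fixed, warped, window = 11L, epsilon = 1e-5) {
  f <- vol_data(fixed); g <- vol_data(warped)
  tm <- ncc_terms(f, g, window, epsilon)
  a1 <- 2 * tm$A / tm$den
  a2 <- 2 * tm$A^2 * tm$B / tm$den^2
  grad <- f * .box_sum3_cpp(a1, tm$r) - .box_sum3_cpp(a1 * tm$muf, tm$r) -
    g * .box_sum3_cpp(a2, tm$r) + .box_sum3_cpp(a2 * tm$mug, tm$r)
  grad / length(f)
}

# the nine forward-difference partials dS_i/dx_j (backward at the far border)
field_partials <- function(field) {
  lapply(1:3, function(i) lapply(1:3, function(j)
    fdiff(field[, , , i], j)))
}

#' Per-voxel Jacobian determinant of the full spatial map
#'
#' Returns `det(I + d s / d p)` at every voxel: the Jacobian of the complete
#' mapping `phi(p) = p + s(p)`, with partial derivatives by forward finite
#' differences (backward at the last index along each axis). The identity
#' (zero) field yields 1 everywhere; values <= 0 mark folding voxels, where
#' the map is locally non-injective.
#'
#' @param field X x Y x Z x 3 displacement array (voxel units).
#' @return 3D array of determinants.
#' @export
jacobian_determinant_map <- function(field) {
  field <- as_field(field)
  if (any(dim(field)[1:3] < 2L))
    stop("field must span at least 2 voxels per axis", call. = FALSE)
  D <- field_partials(field)
  J11 <- 1 + D[[1]][[1]]; J12 <- D[[1]][[2]]; J13 <- D[[1]][[3]]
  J21 <- D[[2]][[1]]; J22 <- 1 + D[[2]][[2]]; J23 <- D[[2]][[3]]
  J31 <- D[[3]][[1]]; J32 <- D[[3]][[2]]; J33 <- 1 + D[[3]][[3]]
  J11 * (J22 * J33 - J23 * J32) -
    J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
}

#' Jacobian folding penalty
#'
#' `sum(|det J| - det J)` over all voxels: exactly 0 when every determinant
#' is >= 0, and twice the absolute determinant summed over folding voxels
#' otherwise, so only locally non-injective transforms are penalized. The
#' penalty admits a subgradient and is usable inside gradient-based
#' optimization.
#'
#' @inheritParams jacobian_determinant_map
#' @return nonnegative scalar.
#' @export
jac_penalty <- function(field) {
  d <- jacobian_determinant_map(field)
  sum(abs(d) - d)
}

# subgradient of jac_penalty w.r.t. the field, via cofactors of J
jac_penalty_grad <- function(field) {
  field <- as_field(field)
  D <- field_partials(field)
  J <- list(
    list(1 + D[[1]][[1]], D[[1]][[2]], D[[1]][[3]]),
    list(D[[2]][[1]], 1 + D[[2]][[2]], D[[2]][[3]]),
    list(D[[3]][[1]], D[[3]][[2]], 1 + D[[3]][[3]])
  )
  det <- J[[1]][[1]] * (J[[2]][[2]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[2]]) -
    J[[1]][[2]] * (J[[2]][[1]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[1]]) +
    J[[1]][[3]] * (J[[2]][[1]] * J[[3]][[2]] - J[[2]][[2]] * J[[3]][[1]])
  coef <- ifelse(det < 0, -2, 0)  # d(|d| - d)/dd
  cof <- function(i, j) {
    r <- setdiff(1:3, i); c <- setdiff(1:3, j)
    (-1)^(i + j) * (J[[r[1]]][[c[1]]] * J[[r[2]]][[c[2]]] -
                      J[[r[1]]][[c[2]]] * J[[r[2]]][[c[1]]])
  }
  out <- array(0, dim(field))
  for (i in 1:3) {
    gi <- array(0, dim(field)[1:3])
    for (j in 1:3) gi <- gi + fdiff_adj(coef * cof(i, j), j)
    out[, , , i] <- gi
  }
  out
}

#' First-derivative smoothness penalty
#'
#' Sum over voxels of the squared Frobenius norm of the finite-difference
#' gradient of the field (all nine partials, same difference scheme as
#' [jacobian_determinant_map()]). Zero for any constant field.
#'
#' @inheritParams jacobian_determinant_map
#' @return nonnegative scalar.
#' @export
grad_penalty <- function(field) {
  field <- as_field(field)
  D <- field_partials(field)
  s <- 0
  for (i in 1:3) for (j in 1:3) s <- s + sum(D[[i]][[j]]^2)
  s
}

grad_penalty_grad <- function(field) {
  field <- as_field(field)
  D <- field_partials(field)
  out <- array(0, dim(field))
  for (i in 1:3) {
    gi <- array(0, dim(field)[1:3])
    for (j in 1:3) gi <- gi + fdiff_adj(2 * D[[i]][[j]], j)
    out[, , , i] <- gi
  }
  out
}

#' Composite registration loss for one pair
#'
#' `total = sim_loss + beta * jac_penalty + alpha * grad_penalty`, together
#' with the folding-voxel count (#\{det <= 0\}) of the field.
#'
#' @param fixed,warped volumes or arrays of equal shape.
#' @param field the displacement field that produced `warped`.
#' @param w an [loss_weights()] object.
#' @return an `lw_loss_report`: list with `l_sim`, `r_jac`, `r_der`, `total`,
#'   `folding_count`, plus the weights used.
#' @export
total_loss <- function(fixed, warped, field, w = loss_weights()) {
  stopifnot(inherits(w, "lw_loss_weights"))
  l_sim <- sim_loss(fixed, warped, w$ncc_window, w$epsilon)
  d <- jacobian_determinant_map(field)
  r_jac <- sum(abs(d) - d)
  r_der <- grad_penalty(field)
  structure(list(
    l_sim = l_sim, r_jac = r_jac, r_der = r_der,
    total = l_sim + w$beta * r_jac + w$alpha * r_der,
    folding_count = sum(d <= 0),
    alpha = w$alpha, beta = w$beta, window = w$ncc_window
  ), class = "lw_loss_report")
}

#' @export
print.lw_loss_report <- function(x, ...) {
  cat(sprintf(
    "<lw_loss_report> total %.6g = sim %.6g + %.1g*jac %.6g + %.1g*der %.6g; folding %d\n",
    x$total, x$l_sim, x$beta, x$r_jac, x$alpha, x$r_der, x$folding_count))
  invisible(x)
}

#' Serialize a loss report to a JSON file
#' @param report an `lw_loss_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loss_report <- function(report, path) {
  stopifnot(inherits(report, "lw_loss_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
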