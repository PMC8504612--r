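# Independent scalar-loop oracles. These deliberately avoid the package's
# vectorized/C++ code paths: plain R loops, stats::dist-free arithmetic and
# base determinants, so agreement is a genuine cross-check.

# trilinear sample of a 3D array at one 0-based coordinate, clamped
bf_sample_trilinear <- function(vol, p) {
  d <- dim(vol)
  p <- pmin(pmax(p, 0), d - 1)
  i0 <- pmin(pmax(floor(p), 0), d - 2)
  f <- p - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) f[1] else 1 - f[1]) *
           (if (dy) f[2] else 1 - f[2]) *
           (if (dz) f[3] else 1 - f[3])
    acc <- acc + wgt * vol[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  acc
}

bf_warp_trilinear <- function(vol, field) {
  d <- dim(vol)
  out <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    p <- c(i - 1, j - 1, k - 1) + field[i, j, k, ]
    out[i, j, k] <- bf_sample_trilinear(vol, p)
  }
  out
}

bf_warp_nearest <- function(vol, field) {
  d <- dim(vol)
  out <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    p <- c(i - 1, j - 1, k - 1) + field[i, j, k, ]
    q <- pmin(pmax(floor(p + 0.5), 0), d - 1)
    out[i, j, k] <- vol[q[1] + 1, q[2] + 1, q[3] + 1]
  }
  out
}

# windowed squared NCC by explicit per-voxel window extraction
bf_local_ncc <- function(f, g, window, epsilon = 1e-5) {
  d <- dim(f)
  r <- (window - 1) %/% 2
  acc <- 0
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    xi <- max(1, i - r):min(d[1], i + r)
    yi <- max(1, j - r):min(d[2], j + r)
    zi <- max(1, k - r):min(d[3], k + r)
    fw <- f[xi, yi, zi]; gw <- g[xi, yi, zi]
    A <- sum((fw - mean(fw)) * (gw - mean(gw)))
    B <- sum((fw - mean(fw))^2)
    C <- sum((gw - mean(gw))^2)
    acc <- acc + A^2 / (B * C + epsilon)
  }
  acc / prod(d)
}

# forward difference with backward fallback at the far border, one scalar line
bf_diff_at <- function(v, i) if (i < length(v)) v[i + 1] - v[i] else v[i] - v[i - 1]

# per-voxel Jacobian of phi = id + s via base::det on explicit 3x3 matrices
bf_jacobian_map <- function(field) {
  d <- dim(field)[1:3]
  out <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    J <- diag(3)
    for (comp in 1:3) {
      J[comp, 1] <- J[comp, 1] + bf_diff_at(field[, j, k, comp], i)
      J[comp, 2] <- J[comp, 2] + bf_diff_at(field[i, , k, comp], j)
      J[comp, 3] <- J[comp, 3] + bf_diff_at(field[i, j, , comp], k)
    }
    out[i, j, k] <- det(J)
  }
  out
}

bf_jac_penalty <- function(field) {
  d <- bf_jacobian_map(field)
  sum(abs(d) - d)
}

bf_grad_penalty <- function(field) {
  d <- dim(field)[1:3]
  acc <- 0
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    for (comp in 1:3) {
      acc <- acc + bf_diff_at(field[, j, k, comp], i)^2 +
        bf_diff_at(field[i, , k, comp], j)^2 +
        bf_diff_at(field[i, j, , comp], k)^2
    }
  }
  acc
}

# direct Eq-style TPS evaluation: explicit loop over kernel terms
bf_evaluate_tps <- function(t, pts) {
  out <- matrix(0, nrow(pts), 3)
  for (m in seq_len(nrow(pts))) {
    p <- pts[m, ]
    val <- t$affine[1, ] + t$affine[2, ] * p[1] + t$affine[3, ] * p[2] +
      t$affine[4, ] * p[3]
    for (i in seq_len(nrow(t$control_src))) {
      r <- sqrt(sum((t$control_src[i, ] - p)^2))
      u <- if (r > 0) r^2 * log(r) else 0
      val <- val + t$weights[i, ] * u
    }
    out[m, ] <- val
  }
  out
}

# smooth random displacement field (sum of low-frequency sinusoids)
smooth_field <- function(shape, amp = 0.5, seed = 1) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(shape[1]) - 1, y = seq_len(shape[2]) - 1,
                   z = seq_len(shape[3]) - 1)
  field <- array(0, c(shape, 3))
  for (c in 1:3) {
    ph <- runif(3, 0, 2 * pi)
    fr <- runif(3, 0.5, 1.5)
    field[, , , c] <- amp * array(
      sin(2 * pi * fr[1] * g$x / shape[1] + ph[1]) *
        sin(2 * pi * fr[2] * g$y / shape[2] + ph[2]) *
        sin(2 * pi * fr[3] * g$z / shape[3] + ph[3]), shape)
  }
  field
}

rand_vol <- function(shape, seed = 1) {
  set.seed(seed)
  array(runif(prod(shape)), shape)
}
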