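lattice3 <- function(n = 3) {
  ax <- seq(0, 1, length.out = n)
  unname(as.matrix(expand.grid(ax, ax, ax)))
}

test_that("identity correspondences give zero weights and an identity affine", {
  src <- lattice3()
  t0 <- fit_tps(src, src)
  expect_lt(max(abs(t0$weights)), 1e-10)
  expect_equal(t0$affine, rbind(0, diag(3)), tolerance = 1e-10)
})

test_that("pure translations are reproduced with zero radial weights", {
  src <- lattice3()
  tt <- fit_tps(src, src + rep(c(0.1, -0.2, 0.05), each = nrow(src)))
  expect_lt(max(abs(tt$weights)), 1e-9)
  p <- matrix(runif(30), 10, 3)
  expect_equal(evaluate_tps(tt, p), p + rep(c(0.1, -0.2, 0.05), each = 10),
               tolerance = 1e-9)
})

test_that("TPS reproduces general affine maps exactly", {
  src <- lattice3()
  A <- matrix(c(1.1, 0.05, 0, -0.1, 0.9, 0.02, 0.03, 0, 1.05), 3, 3)
  b <- c(0.02, -0.01, 0.03)
  dst <- sweep(src %*% t(A), 2, b, `+`)
  tt <- fit_tps(src, dst)
  p <- matrix(runif(60), 20, 3)
  expect_equal(evaluate_tps(tt, p), sweep(p %*% t(A), 2, b, `+`),
               tolerance = 1e-6)
})

test_that("fitted transforms interpolate all control points", {
  set.seed(11)
  src <- lattice3()
  dst <- src + matrix(runif(nrow(src) * 3, -0.08, 0.08), ncol = 3)
  tt <- fit_tps(src, dst)
  expect_lt(max(abs(evaluate_tps(tt, src) - dst)), 1e-8)
})

test_that("the orthogonality side conditions P'w = 0 hold after every fit", {
  for (seed in 1:4) {
    tt <- random_grid_tps(3, 0.08, seed = seed)
    P <- cbind(1, tt$control_src)
    expect_lt(max(abs(t(P) %*% tt$weights)), 1e-6)
  }
})

test_that("evaluate_tps matches a brute-force kernel-sum evaluation", {
  tt <- random_grid_tps(3, 0.07, seed = 21)
  pts <- matrix(runif(45), 15, 3)
  expect_equal(evaluate_tps(tt, pts), bf_evaluate_tps(tt, pts),
               tolerance = 1e-10)
})

test_that("degenerate control configurations raise a solver error", {
  src <- lattice3()
  expect_error(fit_tps(src[c(1, 1, 2, 3, 4), ], src[c(1, 1, 2, 3, 4), ]),
               "duplicate")
  coplanar <- cbind(matrix(runif(12), 6, 2), 0.5)
  expect_error(suppressMessages(fit_tps(coplanar, coplanar + 0.01)),
               "singular")
  expect_error(fit_tps(src[1:4, ], src[1:4, ]), "at least 5")
})

test_that("random_grid_tps is seeded, sized and identity at h = 0", {
  t0 <- random_grid_tps(5, 0, seed = 1)
  expect_equal(nrow(t0$control_src), 125L)
  p <- matrix(runif(15), 5, 3)
  expect_equal(evaluate_tps(t0, p), p, tolerance = 1e-9)
  ta <- random_grid_tps(5, 0.05, seed = 42)
  tb <- random_grid_tps(5, 0.05, seed = 42)
  tc <- random_grid_tps(5, 0.05, seed = 43)
  expect_identical(ta$control_dst, tb$control_dst)
  expect_false(identical(ta$control_dst, tc$control_dst))
})

test_that("identity-transform warps reproduce the input exactly", {
  v <- lw_volume(rand_vol(c(6, 6, 6), seed = 2))
  t0 <- fit_tps(lattice3(), lattice3())
  expect_equal(warp_volume_tps(v, t0)$data, v$data, tolerance = 1e-9)
})

test_that("a one-voxel translation shifts the interior as backward mapping", {
  d <- c(8, 8, 8)
  v <- rand_vol(d, seed = 3)
  # map f(x) = x + 1/(d-1) in normalized x: output(i) = input(i+1)
  src <- lattice3()
  tt <- fit_tps(src, src + rep(c(1 / (d[1] - 1), 0, 0), each = nrow(src)))
  out <- warp_volume_tps(v, tt)
  expect_equal(out[1:7, , ], v[2:8, , ], tolerance = 1e-9)
})

test_that("TPS warps agree with the scalar-loop resampler on 16^3", {
  d <- c(16, 16, 16)
  v <- rand_vol(d, seed = 4)
  tt <- random_grid_tps(4, 0.05, seed = 5)
  got <- warp_volume_tps(v, tt)
  want <- bf_warp_trilinear(v, tps_displacement_field(tt, d))
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("warp_pair_tps equals two independent single warps", {
  v1 <- lw_volume(rand_vol(c(8, 8, 8), seed = 6))
  v2 <- lw_volume(rand_vol(c(8, 8, 8), seed = 7))
  tt <- random_grid_tps(3, 0.06, seed = 8)
  wp <- lungwarp:::warp_pair_tps(v1, v2, tt)
  expect_equal(wp$moving$data, warp_volume_tps(v1, tt)$data)
  expect_equal(wp$fixed$data, warp_volume_tps(v2, tt)$data)
})
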