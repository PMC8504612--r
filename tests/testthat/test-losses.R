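test_that("identical non-constant volumes score NCC ~ 1 and sim ~ 0", {
  v <- rand_vol(c(10, 10, 10), seed = 1)
  expect_equal(local_ncc(v, v, 5), 1, tolerance = 1e-4)
  expect_lt(sim_loss(v, v, 5), 1e-4)
})

test_that("NCC is invariant to positive affine intensity maps", {
  v <- rand_vol(c(10, 10, 10), seed = 2)
  expect_equal(local_ncc(v, 3 * v + 0.7, 5), 1, tolerance = 1e-4)
  expect_equal(local_ncc(2 * v - 1, v, 5), 1, tolerance = 1e-4)
})

test_that("anticorrelated images still score sim ~ 0 (squared correlation)", {
  v <- rand_vol(c(9, 9, 9), seed = 3)
  expect_lt(sim_loss(v, 1 - v, 5), 1e-4)
})

test_that("local_ncc matches the brute-force windowed loop oracle", {
  f <- rand_vol(c(12, 12, 12), seed = 4)
  g <- rand_vol(c(12, 12, 12), seed = 5)
  expect_lt(abs(local_ncc(f, g, 5) - bf_local_ncc(f, g, 5)), 1e-6)
  expect_lt(abs(local_ncc(f, g, 7) - bf_local_ncc(f, g, 7)), 1e-6)
  got <- sim_loss(f, g, 5)
  expect_gt(got, 0); expect_lte(got, 1)
})

test_that("NCC and sim lie in [0, 1]", {
  for (seed in 1:3) {
    f <- rand_vol(c(8, 8, 8), seed = seed)
    g <- rand_vol(c(8, 8, 8), seed = seed + 7)
    n <- local_ncc(f, g, 5)
    expect_gte(n, 0); expect_lte(n, 1)
  }
})

test_that("the zero field has unit determinants and zero penalties", {
  z <- array(0, c(8, 8, 8, 3))
  expect_equal(jacobian_determinant_map(z), array(1, c(8, 8, 8)))
  expect_identical(jac_penalty(z), 0)
  expect_identical(grad_penalty(z), 0)
  expect_identical(folding_count(z), 0L)
})

test_that("linear fields give the analytic determinant everywhere", {
  d <- c(8, 8, 8)
  g <- lungwarp:::voxel_grid(d)
  A <- diag(c(2, 1, 1))
  lin <- array(g %*% t(A - diag(3)), c(d, 3))
  expect_equal(jacobian_determinant_map(lin), array(2, d))
  A2 <- matrix(c(1.2, 0.1, 0, 0.05, 0.9, 0.1, 0, 0.02, 1.1), 3, 3, byrow = TRUE)
  lin2 <- array(g %*% t(A2 - diag(3)), c(d, 3))
  expect_equal(jacobian_determinant_map(lin2), array(det(A2), d),
               tolerance = 1e-12)
})

test_that("a locally flipped field is detected as folding", {
  d <- c(8, 8, 8)
  field <- array(0, c(d, 3))
  field[5, 4, 4, 1] <- -1.5   # det = 1 + dsx/dx = -0.5 at (4,4,4)
  dets <- jacobian_determinant_map(field)
  expect_equal(dets[4, 4, 4], -0.5)
  expect_gte(folding_count(field), 1L)
  expect_equal(jac_penalty(field), 1)   # 2 * |-0.5|
  expect_gt(jac_penalty(field), 0)
})

test_that("shrinking a folded field toward zero de-activates the penalty", {
  d <- c(8, 8, 8)
  field <- array(0, c(d, 3))
  field[5, 4, 4, 1] <- -1.5
  pens <- vapply(c(1, 0.8, 0.7, 0.5, 0.2, 0),
                 function(s) jac_penalty(field * s), numeric(1))
  expect_true(all(diff(pens) <= 1e-12))
  expect_identical(pens[length(pens)], 0)
})

test_that("penalties match the brute-force per-voxel oracles", {
  f <- smooth_field(c(10, 10, 10), amp = 1.5, seed = 6)
  expect_lt(abs(jac_penalty(f) - bf_jac_penalty(f)), 1e-6)
  expect_lt(abs(grad_penalty(f) - bf_grad_penalty(f)), 1e-6)
  expect_lt(max(abs(jacobian_determinant_map(f) - bf_jacobian_map(f))), 1e-9)
})

test_that("grad_penalty has the closed form c^2 n^3 on a linear ramp", {
  n <- 8; c0 <- 0.1
  g <- lungwarp:::voxel_grid(c(n, n, n))
  f <- array(0, c(n, n, n, 3))
  f[, , , 1] <- array(c0 * g[, 1], c(n, n, n))
  expect_equal(grad_penalty(f), c0^2 * n^3, tolerance = 1e-12)
})

test_that("penalties are invariant to constant field offsets", {
  f <- smooth_field(c(8, 8, 8), amp = 0.8, seed = 7)
  f2 <- f
  for (c in 1:3) f2[, , , c] <- f2[, , , c] + c(2, -1, 0.5)[c]
  expect_equal(jac_penalty(f2), jac_penalty(f), tolerance = 1e-9)
  expect_equal(grad_penalty(f2), grad_penalty(f), tolerance = 1e-9)
})

test_that("penalty subgradients match numerical differentiation", {
  d <- c(6, 6, 6)
  set.seed(8)
  f <- array(rnorm(prod(d) * 3, 0, 0.5), c(d, 3))
  gj <- lungwarp:::jac_penalty_grad(f)
  gd <- lungwarp:::grad_penalty_grad(f)
  h <- 1e-6
  for (i in sample(length(f), 8)) {
    fp <- f; fp[i] <- fp[i] + h
    fm <- f; fm[i] <- fm[i] - h
    expect_equal(gj[i], (jac_penalty(fp) - jac_penalty(fm)) / (2 * h),
                 tolerance = 1e-4)
    expect_equal(gd[i], (grad_penalty(fp) - grad_penalty(fm)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("the NCC gradient matches numerical differentiation", {
  d <- c(6, 6, 6)
  f <- rand_vol(d, seed = 9)
  g <- rand_vol(d, seed = 10)
  gr <- lungwarp:::ncc_grad_warped(f, g, 5L, 1e-5)
  h <- 1e-6
  for (i in sample(length(g), 8)) {
    gp <- g; gp[i] <- gp[i] + h
    gm <- g; gm[i] <- gm[i] - h
    expect_equal(gr[i], (local_ncc(f, gp, 5) - local_ncc(f, gm, 5)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("total_loss composes its components with the stated weights", {
  d <- c(8, 8, 8)
  m <- rand_vol(d, seed = 11)
  f <- rand_vol(d, seed = 12)
  s <- smooth_field(d, amp = 0.5, seed = 13)
  warped <- warp_trilinear(m, s)
  w <- loss_weights(alpha = 1, beta = 1e-5, ncc_window = 5)
  rep <- total_loss(f, warped, s, w)
  expect_equal(rep$total, rep$l_sim + 1e-5 * rep$r_jac + 1 * rep$r_der,
               tolerance = 1e-12)
  expect_equal(rep$l_sim, sim_loss(f, warped, 5))
  expect_equal(rep$r_jac, jac_penalty(s))
  expect_equal(rep$r_der, grad_penalty(s))
  expect_identical(rep$folding_count, folding_count(s))
  # identical volumes, zero field
  z <- array(0, c(d, 3))
  rep0 <- total_loss(f, f, z, w)
  expect_lt(rep0$total, 1e-4)
  expect_identical(rep0$folding_count, 0L)
  # beta = 0 makes the total independent of folding
  w0 <- loss_weights(alpha = 1, beta = 0, ncc_window = 5)
  fold <- array(0, c(d, 3)); fold[5, 4, 4, 1] <- -1.5
  repf <- total_loss(f, warp_trilinear(m, fold), fold, w0)
  expect_equal(repf$total, repf$l_sim + repf$r_der, tolerance = 1e-12)
  expect_gte(repf$folding_count, 1L)
})

test_that("jac_penalty is zero iff folding_count is zero (strict positivity)", {
  for (seed in 1:4) {
    f <- smooth_field(c(8, 8, 8), amp = ifelse(seed %% 2, 0.3, 3), seed = seed)
    d <- jacobian_determinant_map(f)
    if (all(d > 0)) {
      expect_identical(jac_penalty(f), 0)
      expect_identical(folding_count(f), 0L)
    } else {
      expect_gt(jac_penalty(f), 0)
      expect_gte(folding_count(f), 1L)
    }
  }
})

test_that("loss reports serialize to JSON", {
  d <- c(6, 6, 6)
  rep <- total_loss(rand_vol(d, 1), rand_vol(d, 2), array(0, c(d, 3)),
                    loss_weights(ncc_window = 5))
  path <- tempfile(fileext = ".json")
  write_loss_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$total, rep$total, tolerance = 1e-12)
  expect_equal(back$folding_count, 0L)
})

test_that("loss_weights validates its invariants", {
  expect_error(loss_weights(ncc_window = 4), "odd")
  expect_error(loss_weights(ncc_window = 1), "odd")
  expect_error(loss_weights(alpha = -1), ">= 0")
})
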