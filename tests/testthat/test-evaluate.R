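test_that("TRE identities: coincident landmarks, unit shift with spacing", {
  pts <- matrix(c(2, 3, 4, 5, 6, 7), 2, 3, byrow = TRUE)
  lf <- lw_landmarks(pts, "fixed")
  lm <- lw_landmarks(pts, "moving")
  z <- array(0, c(10, 10, 10, 3))
  expect_equal(tre(lf, lm, z, c(1, 1, 1)), c(mean = 0, sd = 0))
  # moving = fixed + 1 voxel along x at spacing (0.97, 0.97, 2.5)
  lm1 <- lw_landmarks(pts + rep(c(1, 0, 0), each = 2), "moving")
  got <- tre(lf, lm1, z, c(0.97, 0.97, 2.5))
  expect_equal(got[["mean"]], 0.97, tolerance = 1e-12)
  expect_equal(got[["sd"]], 0)
  # and the zero-field baseline without a field argument
  expect_equal(tre(lf, lm1, NULL, c(0.97, 0.97, 2.5))[["mean"]], 0.97)
})

test_that("TRE contract errors: count mismatch and out-of-grid landmarks", {
  lf <- lw_landmarks(matrix(1, 2, 3), "fixed")
  lm <- lw_landmarks(matrix(1, 3, 3), "moving")
  z <- array(0, c(4, 4, 4, 3))
  expect_error(tre(lf, lm, z), "equal point counts")
  out <- lw_landmarks(matrix(c(9, 1, 1), 1, 3), "fixed")
  expect_error(tre(out, lw_landmarks(matrix(1, 1, 3), "moving"), z),
               "outside")
})

test_that("the ground-truth field reproduces its own landmarks exactly", {
  pr <- make_pair(c(16, 16, 16), h = 0.05, n_landmarks = 15, seed = 21)
  got <- tre(pr$landmarks_fixed, pr$landmarks_moving, pr$gt_field)
  expect_lt(got[["mean"]], 1e-8)
  init <- tre(pr$landmarks_fixed, pr$landmarks_moving)
  expect_gt(init[["mean"]], 0)
})

test_that("dice identities and the shifted-cube case", {
  d <- c(8, 8, 8)
  a <- array(0, d); a[2:3, 2:3, 2:3] <- 1        # 8-voxel cube
  expect_equal(dice(a, a), 1)
  b <- array(0, d); b[6:7, 6:7, 6:7] <- 1
  expect_equal(dice(a, b), 0)
  shifted <- array(0, d); shifted[2:3, 2:3, 3:4] <- 1  # overlaps in 4 voxels
  expect_equal(dice(a, shifted), 0.5)
  expect_identical(dice(a, shifted), dice(shifted, a))
  expect_message(got <- dice(array(0, d), array(0, d)), "empty")
  expect_equal(got, 1)
  expect_error(dice(a, array(0, c(4, 4, 4))), "shape")
})

test_that("dice is symmetric on random masks", {
  for (seed in 1:3) {
    a <- (rand_vol(c(8, 8, 8), seed) > 0.5) * 1
    b <- (rand_vol(c(8, 8, 8), seed + 5) > 0.5) * 1
    expect_identical(dice(a, b), dice(b, a))
  }
})

test_that("folding_count on analytic fields", {
  d <- c(8, 8, 8)
  expect_identical(folding_count(array(0, c(d, 3))), 0L)
  g <- lungwarp:::voxel_grid(d)
  neg <- array(g %*% t(diag(c(-1, 1, 1)) - diag(3)), c(d, 3))
  expect_identical(folding_count(neg), as.integer(prod(d)))
  one <- array(0, c(d, 3)); one[5, 4, 4, 1] <- -1.5
  expect_gte(folding_count(one), 1L)
  # zero folding implies zero jacobian penalty (shared determinant map)
  sm <- smooth_field(d, amp = 0.2, seed = 3)
  if (folding_count(sm) == 0L) expect_identical(jac_penalty(sm), 0)
})

test_that("an identity (zero-output) network reproduces the initial TRE", {
  man <- toy_suite()
  net <- build_network(toy_net_cfg(), seed = 1)
  net$params$head$w[] <- 0
  net$params$head$b[] <- 0
  tab <- evaluate_testset(net, man[1:3, ])
  pp <- tab[tab$pair_id != "summary", ]
  expect_equal(pp$tre_mean_mm, pp$initial_tre_mean_mm, tolerance = 1e-12)
  expect_equal(pp$dice, pp$initial_dice, tolerance = 1e-12)
  expect_true(all(pp$folding_count == 0))
})

test_that("evaluate_testset returns per-pair records plus a summary row", {
  man <- toy_suite()
  ck <- toy_checkpoint()
  out_csv <- tempfile(fileext = ".csv")
  tab <- evaluate_testset(ck, man, out_csv = out_csv)
  expect_equal(nrow(tab), nrow(man) + 1L)
  expect_identical(tab$pair_id[nrow(tab)], "summary")
  pp <- tab[tab$pair_id != "summary", ]
  expect_equal(tab$dice[nrow(tab)], mean(pp$dice))
  expect_true(all(pp$dice >= 0 & pp$dice <= 1))
  expect_true(all(pp$tre_mean_mm >= 0))
  expect_true(file.exists(out_csv))
})

test_that("unreadable pairs are skipped with a warning; empty input is empty", {
  man <- toy_suite()
  bad <- man[1:2, ]
  bad$moving[2] <- file.path(tempdir(), "nope.nii.gz")
  expect_warning(tab <- evaluate_testset(toy_checkpoint(), bad), "skipping")
  expect_equal(sum(tab$pair_id != "summary"), 1L)
  empty <- evaluate_testset(toy_checkpoint(), man[0, ])
  expect_equal(nrow(empty), 0L)
})
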