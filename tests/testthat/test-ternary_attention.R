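test_that("tensor-form attention map equals the triple-loop oracle", {
  worst <- 0
  for (seed in 1:50) {
    inst <- random_tan_instance(seed)
    for (head in 1:2) {
      A <- tan_attention_map(inst$Xp, inst$Xt, inst$Xe, inst$params, head)
      ref <- oracle_attention_map(inst$Xp, inst$Xt, inst$Xe, inst$params,
                                  head)
      expect_equal(dim(A$tensor),
                   c(ncol(inst$Xp), ncol(inst$Xt), ncol(inst$Xe)))
      worst <- max(worst, max(abs(A$tensor - ref)))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("vectorized fusion equals the quadruple-loop oracle", {
  worst <- 0
  for (seed in 1:50) {
    inst <- random_tan_instance(seed)
    A <- tan_attention_map(inst$Xp, inst$Xt, inst$Xe, inst$params, 1)
    f <- tan_fusion(inst$Xp, inst$Xt, inst$Xe, inst$params, 1, A = A)
    ref <- oracle_fusion(inst$Xp, inst$Xt, inst$Xe, A$tensor, inst$params)
    worst <- max(worst, max(abs(f - ref)))
  }
  expect_lt(worst, 1e-6)
})

test_that("zero attention weight vector annihilates map and fusion", {
  inst <- random_tan_instance(3)
  inst$params$q_heads[[1]][] <- 0
  A <- tan_attention_map(inst$Xp, inst$Xt, inst$Xe, inst$params, 1)
  expect_true(all(A$tensor == 0))
  expect_true(all(tan_fusion(inst$Xp, inst$Xt, inst$Xe, inst$params, 1) == 0))
})

test_that("single-substructure fusion reduces to its closed form", {
  set.seed(5)
  params <- tan_parameters(3, 3, 3, kappa = 4, heads = 1, seed = 5)
  xp <- matrix(rnorm(3), 3); xt <- matrix(rnorm(3), 3); xe <- matrix(rnorm(3), 3)
  A <- tan_attention_map(xp, xt, xe, params, 1)
  f <- tan_fusion(xp, xt, xe, params, 1)
  zp <- pmax(drop(crossprod(xp, params$U)), 0)
  zt <- pmax(drop(crossprod(xt, params$W)), 0)
  ze <- pmax(drop(crossprod(xe, params$V)), 0)
  expect_equal(f, A$tensor[1, 1, 1] * zp * zt * ze)
})

test_that("multi-head fusion sums heads and degenerates correctly", {
  inst <- random_tan_instance(9)
  mh <- tan_multi_head(inst$Xp, inst$Xt, inst$Xe, inst$params)
  expect_length(mh$maps, 2L)
  f1 <- tan_fusion(inst$Xp, inst$Xt, inst$Xe, inst$params, 1)
  f2 <- tan_fusion(inst$Xp, inst$Xt, inst$Xe, inst$params, 2)
  expect_equal(mh$f_sum, f1 + f2, tolerance = 1e-10)

  # zeroing the second head's q leaves only head 1
  inst$params$q_heads[[2]][] <- 0
  mh2 <- tan_multi_head(inst$Xp, inst$Xt, inst$Xe, inst$params)
  expect_equal(mh2$f_sum, f1, tolerance = 1e-10)

  one_head <- inst$params
  one_head$q_heads <- one_head$q_heads[1]
  one_head$heads <- 1L
  mh1 <- tan_multi_head(inst$Xp, inst$Xt, inst$Xe, one_head)
  expect_equal(mh1$f_sum, f1, tolerance = 1e-10)
})

test_that("parameter count follows kappa(Dp+Dt+De) + heads*kappa", {
  expect_equal(tan_param_count(d_p = 64, d_t = 64, d_e = 64, kappa = 256,
                               heads = 2), 49664L)
  p2 <- tan_parameters(5, 6, 7, kappa = 8, heads = 3, seed = 1)
  expect_equal(tan_param_count(p2), 8L * (5L + 6L + 7L) + 3L * 8L)
  # each extra head adds exactly kappa parameters
  p3 <- tan_parameters(5, 6, 7, kappa = 8, heads = 4, seed = 1)
  expect_equal(tan_param_count(p3) - tan_param_count(p2), 8L)
})

test_that("average pooling computes window means and preserves the mean", {
  expect_equal(tan_pool(c(1, 3, 5, 7), 2), c(2, 6))
  f <- rnorm(12)
  expect_equal(tan_pool(f, 1), f)
  expect_equal(mean(tan_pool(f, 3)), mean(f), tolerance = 1e-9)
  expect_error(tan_pool(f, 5), "divide")
})

test_that("collapsing the third entity reproduces bilinear attention", {
  for (seed in c(2, 13, 31)) {
    inst <- random_tan_instance(seed)
    br <- tan_bilinear_reduction(inst$Xp, inst$Xt, inst$params, 1)
    ref <- oracle_bilinear(inst$Xp, inst$Xt, inst$params, 1)
    expect_lt(max(abs(br$map - ref$map)), 1e-6)
    expect_lt(max(abs(br$f - ref$f)), 1e-6)
    expect_equal(dim(br$map), c(ncol(inst$Xp), ncol(inst$Xt)))
    expect_length(br$f, inst$params$kappa)
  }
  # q = 0 gives zero map and zero fusion
  inst <- random_tan_instance(4)
  inst$params$q_heads[[1]][] <- 0
  br0 <- tan_bilinear_reduction(inst$Xp, inst$Xt, inst$params, 1)
  expect_true(all(br0$map == 0) && all(br0$f == 0))
})

test_that("permuting POI columns permutes the map and fixes the fusion", {
  set.seed(77)
  params <- tan_parameters(4, 3, 5, kappa = 6, heads = 1, seed = 77)
  Xp <- matrix(rnorm(4 * 5), 4); Xt <- matrix(rnorm(3 * 4), 3)
  Xe <- matrix(rnorm(5 * 2), 5)
  perm <- c(3, 1, 5, 2, 4)
  A <- tan_attention_map(Xp, Xt, Xe, params, 1)
  Ap <- tan_attention_map(Xp[, perm], Xt, Xe, params, 1)
  expect_equal(Ap$tensor, A$tensor[perm, , ], tolerance = 1e-12)
  expect_equal(tan_fusion(Xp[, perm], Xt, Xe, params, 1),
               tan_fusion(Xp, Xt, Xe, params, 1), tolerance = 1e-10)
})

test_that("nonnegative q yields a nonnegative attention map under ReLU", {
  for (seed in 1:10) {
    inst <- random_tan_instance(seed + 200)
    inst$params$q_heads[[1]] <- abs(inst$params$q_heads[[1]])
    A <- tan_attention_map(inst$Xp, inst$Xt, inst$Xe, inst$params, 1)
    expect_true(all(A$tensor >= 0))
    expect_true(all(is.finite(A$tensor)))
  }
})

test_that("dimension mismatches name the offending axis", {
  inst <- random_tan_instance(1)
  bad <- rbind(inst$Xp, 0)
  expect_error(tan_attention_map(bad, inst$Xt, inst$Xe, inst$params, 1),
               "POI axis")
  bad_e <- rbind(inst$Xe, 0)
  expect_error(tan_attention_map(inst$Xp, inst$Xt, bad_e, inst$params, 1),
               "E3 axis")
})
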