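test_that("spike NLL matches hand-evaluated Poisson terms", {
  expect_equal(spike_nll(0, 2), 2.0)
  expect_equal(spike_nll(3, 3), 3 - 3 * log(3) + log(6))
  # mean over entries
  X <- array(c(0, 3), dim = c(1, 2, 1))
  lam <- array(c(2, 3), dim = c(1, 2, 1))
  expect_equal(spike_nll(X, lam), (2 + 3 - 3 * log(3) + log(6)) / 2)
  expect_error(spike_nll(c(1, 2), c(1, -1)), "positive")
  expect_error(spike_nll(array(0, c(2, 2, 2)), array(1, c(2, 2, 1))),
               "shape")
})

test_that("rate R2 has the standard anchor points", {
  set.seed(3)
  Y <- array(runif(5 * 8 * 4, 0.1, 2), dim = c(5, 8, 4))
  expect_equal(rate_r2(Y, Y), 1.0)
  means <- apply(Y, 3, mean)
  Ybar <- aperm(array(means, dim = c(4, 5, 8)), c(2, 3, 1))
  expect_equal(rate_r2(Y, Ybar), 0.0, tolerance = 1e-12)
  # independent predictions are no better than the mean on average
  r2s <- replicate(20, rate_r2(Y, array(runif(length(Y), 0.1, 2), dim(Y))))
  expect_lt(mean(r2s), 0)
  # zero-variance neurons are excluded with a warning
  Y0 <- Y; Y0[, , 2] <- 1
  expect_warning(rate_r2(Y0, Y0), "zero-variance")
})

test_that("state R2 is exactly 1 under invertible affine maps of the truth", {
  set.seed(11)
  Z <- integrate_system(chaotic_system(), 6, 20, seed = 2)
  for (rep in 1:3) {
    A <- matrix(rnorm(9), 3, 3)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
    b <- rnorm(3)
    Zh <- odinflow:::unflatten_trials(
      odinflow:::flatten_trials(Z) %*% A + matrix(b, 120, 3, byrow = TRUE),
      6, 20)
    sr <- state_r2(Z, Zh)
    expect_equal(sr$r2, 1.0, tolerance = 1e-10)
    expect_equal(sr$map$linear, A, tolerance = 1e-6)
  }
  # pure noise has no linearly explainable variance
  Zn <- array(rnorm(length(Z)), dim = dim(Z))
  expect_lt(abs(state_r2(Z, Zn)$r2), 0.05)
  # a low-dimensional projection of the truth still scores high (documented
  # caveat: State R2 alone cannot certify latent accuracy)
  Zproj <- Z
  Zproj[, , 2] <- Z[, , 1]
  Zproj[, , 3] <- Z[, , 1]
  expect_gt(state_r2(Z, Zproj)$r2, 0.99)
  expect_error(state_r2(Z[1:1, 1:1, , drop = FALSE],
                        Zn[1:1, 1:1, , drop = FALSE]), "fewer points")
})

test_that("effective rank interpolates between integer ranks", {
  expect_equal(effective_rank(diag(5)), 5, tolerance = 1e-12)
  expect_equal(effective_rank(outer(1:4, 2:5)), 1, tolerance = 1e-12)
  expect_equal(effective_rank(diag(c(1, 1, 1e-8))), 2, tolerance = 1e-6)
  expect_equal(effective_rank(3 * diag(4)), 4, tolerance = 1e-12)
  set.seed(4)
  for (rep in 1:5) {
    M <- matrix(rnorm(35), 5, 7)
    er <- effective_rank(M)
    expect_gte(er, 1)
    expect_lte(er, 5)
  }
  expect_error(effective_rank(matrix(0, 3, 3)), "zero matrix")
})

test_that("cycle consistency recovers latents through invertible readouts and degrades with noise", {
  set.seed(21)
  Z <- array(rnorm(30 * 20 * 3), dim = c(30, 20, 3))
  A <- matrix(rnorm(3 * 8), 3, 8)
  L <- odinflow:::unflatten_trials(odinflow:::flatten_trials(Z) %*% A,
                                   30, 20)
  r2 <- cycle_consistency(L, Z, noise_levels = c(0, 2), seed = 1,
                          epochs = 120)
  expect_gt(r2[1], 0.9)
  expect_gt(r2[1], r2[2])
  # constant log-rates carry no information about the latents
  Lconst <- array(1, dim = c(30, 20, 8))
  r2c <- cycle_consistency(Lconst, Z, noise_levels = 0, seed = 1,
                           epochs = 30)
  expect_lt(r2c, 0.1)
  expect_error(cycle_consistency(L, array(0, dim = dim(Z)), 0), "degenerate")
})

test_that("activation recovery is near-perfect for exact affine latents and true rates", {
  gts <- tiny_benchmark(n_trials = 20, T = 25, N = 8, seed = 5)
  set.seed(6)
  A <- matrix(rnorm(9), 3, 3) + diag(3)
  b <- rnorm(3)
  n <- 20 * 25
  Zh <- odinflow:::unflatten_trials(
    odinflow:::flatten_trials(gts$Z) %*% A + matrix(b, n, 3, byrow = TRUE),
    20, 25)
  sr <- state_r2(gts$Z, Zh)
  r2 <- activation_recovery(gts, Zh, gts$Y, sr$map)
  expect_equal(length(r2), 8)
  expect_true(all(r2 > 0.999))
})

test_that("co-bps is zero at the null, positive for the truth, negative when worse", {
  gts <- tiny_benchmark(n_trials = 15, T = 20, N = 6, seed = 9)
  X <- gts$X
  null_rates <- pmax(apply(X, 3, mean), 1e-9)
  expect_equal(co_bps(X, aperm(array(null_rates, dim = c(6, 15, 20)),
                               c(2, 3, 1)), null_rates), 0)
  expect_gt(co_bps(X, gts$Y, null_rates), 0)
  worse <- aperm(array(null_rates * 3, dim = c(6, 15, 20)), c(2, 3, 1))
  expect_lt(co_bps(X, worse, null_rates), 0)
  expect_error(co_bps(array(0L, c(1, 2, 3)), array(1, c(1, 2, 3)),
                      rep(1, 3)), "no spikes")
})

test_that("R2 metrics are invariant to trial permutation", {
  gts <- tiny_benchmark(n_trials = 10, T = 12, N = 5, seed = 14)
  set.seed(15)
  Zh <- gts$Z + array(rnorm(length(gts$Z), sd = 0.1), dim = dim(gts$Z))
  perm <- sample(10)
  expect_equal(state_r2(gts$Z, Zh)$r2,
               state_r2(gts$Z[perm, , ], Zh[perm, , ])$r2, tolerance = 1e-9)
  Yh <- gts$Y * 0.9 + 0.01
  expect_equal(rate_r2(gts$Y, Yh), rate_r2(gts$Y[perm, , ], Yh[perm, , ]),
               tolerance = 1e-9)
})
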