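test_that("analytic gradients match finite differences for every readout", {
  of <- asNamespace("odinflow")
  set.seed(1)
  X <- array(rpois(4 * 9 * 5, 0.5), dim = c(4, 9, 5))
  for (ro in c("linear", "mlp", "flow")) {
    cfg <- model_config(D_hat = 3, readout = ro, encoder_hidden = 6,
                        node_hidden = c(7), readout_hidden = c(8),
                        flow_K = 4, seed = 3)
    m <- init_model(cfg, 5)
    lb <- of$batch_loss(m, X, with_grads = TRUE)
    paths <- of$param_leaf_paths(m$params)
    set.seed(9)
    for (p in paths) {
      leaf <- of$param_get(m$params, p)
      g_an <- of$param_get(lb$grads, p)
      for (k in sample(length(leaf), min(2, length(leaf)))) {
        eps <- 1e-5
        m2 <- m
        pl <- leaf; pl[k] <- pl[k] + eps
        m2$params <- of$param_set(m$params, p, pl)
        up <- of$batch_loss(m2, X)
        pl[k] <- leaf[k] - eps
        m2$params <- of$param_set(m$params, p, pl)
        dn <- of$batch_loss(m2, X)
        g_fd <- (up - dn) / (2 * eps)
        rel <- abs(g_an[k] - g_fd) / max(abs(g_fd), abs(g_an[k]), 1e-6)
        expect_lt(rel, 1e-3)
      }
    }
  }
})

test_that("encoder output has the right shape and batch independence", {
  cfg <- tiny_config("linear")
  m <- init_model(cfg, 6)
  set.seed(2)
  X <- array(rpois(5 * 12 * 6, 1), dim = c(5, 12, 6))
  h <- encode(m, X)
  expect_equal(dim(h), c(5, 2 * cfg$encoder_hidden))
  # permuting trials permutes outputs identically: no cross-trial mixing
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(encode(m, X[perm, , , drop = FALSE]), h[perm, ],
               tolerance = 1e-12)
  # zero recurrent and input weights with zero spikes give a zero state
  m0 <- m
  m0$params$enc_f <- lapply(m0$params$enc_f, function(w) w * 0)
  m0$params$enc_b <- lapply(m0$params$enc_b, function(w) w * 0)
  h0 <- encode(m0, array(0L, dim = c(2, 4, 6)))
  expect_true(all(h0 == 0))
  expect_error(encode(m, array(0L, dim = c(2, 0, 6))), "T >= 1")
})

test_that("initial conditions follow the readout-specific convention", {
  # linear readout: phi is affine; zero weights give zero initial condition
  cfg <- tiny_config("linear")
  m <- init_model(cfg, 6)
  m$params$phi$W <- m$params$phi$W * 0
  m$params$phi$b <- m$params$phi$b * 0
  h <- matrix(rnorm(4 * 2 * cfg$encoder_hidden), 4)
  expect_true(all(init_condition(m, h) == 0))
  # flow readout with a zero update MLP: z0 is the trimmed affine output
  cfgf <- tiny_config("flow")
  mf <- init_model(cfgf, 6)
  mf$params$readout$W <- lapply(mf$params$readout$W, function(w) w * 0)
  mf$params$readout$b <- lapply(mf$params$readout$b, function(b) b * 0)
  a <- h %*% mf$params$phi$W + matrix(mf$params$phi$b, 4, 6, byrow = TRUE)
  expect_equal(init_condition(mf, h), a[, 1:3], tolerance = 1e-12)
  expect_equal(ncol(init_condition(mf, h)), cfgf$D_hat)
})

test_that("the Euler unroll matches closed forms", {
  # zero-initialized final generator layer: trajectory constant at z0
  cfg <- tiny_config("linear")
  m <- init_model(cfg, 6)
  z0 <- matrix(rnorm(6), 2, 3)
  Z <- unroll_dynamics(m, z0, 5)
  expect_equal(dim(Z), c(2, 5, 3))
  for (t in 1:5) expect_equal(Z[, t, ], z0, ignore_attr = TRUE)
  # a purely linear vector field f(z) = z A steps exactly by (I + alpha A)
  cfg2 <- model_config(D_hat = 3, readout = "linear", encoder_hidden = 4,
                       node_hidden = integer(0), seed = 2)
  m2 <- init_model(cfg2, 6)
  A <- matrix(rnorm(9, sd = 0.2), 3, 3)
  m2$params$node$W[[1]] <- A
  m2$params$node$b[[1]] <- rep(0, 3)
  Z2 <- unroll_dynamics(m2, z0, 2)
  M <- diag(3) + 0.1 * A
  expect_equal(Z2[, 1, ], z0 %*% M, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(Z2[, 2, ], z0 %*% M %*% M, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("readout rates are positive and dispatch matches the flow module", {
  set.seed(5)
  for (ro in c("linear", "mlp", "flow")) {
    m <- init_model(tiny_config(ro, seed = 11), 6)
    Z <- array(rnorm(2 * 4 * 3), dim = c(2, 4, 3))
    rr <- readout_rates(m, Z)
    expect_equal(dim(rr$rates), c(2, 4, 6))
    expect_true(all(rr$rates > 0))
    expect_equal(rr$rates, exp(rr$log_rates))
    if (ro == "flow") {
      direct <- flow_forward(m$params$readout, odinflow:::flatten_trials(Z))
      expect_equal(odinflow:::flatten_trials(rr$log_rates), direct,
                   tolerance = 1e-12)
    }
  }
})

test_that("training is well-behaved: zero learning rate is a no-op and loss beats the mean-rate baseline", {
  gts <- tiny_benchmark(seed = 13)
  cfg0 <- tiny_config("linear", epochs = 1, learning_rate = 0)
  m0 <- odinflow:::init_output_bias(
    init_model(cfg0, dim(gts$X)[3]),
    gts$X[gts$dataset$train_idx, , , drop = FALSE])
  t0 <- train_model(gts$dataset, cfg0)
  expect_equal(t0$params, m0$params, tolerance = 1e-12)
  # short real training should beat predicting each neuron's mean count
  cfg <- tiny_config("linear", epochs = 40, seed = 3)
  m <- train_model(gts$dataset, cfg)
  Xv <- gts$X[gts$dataset$valid_idx, , , drop = FALSE]
  mean_rates <- pmax(apply(gts$X[gts$dataset$train_idx, , , drop = FALSE],
                           3, mean), 1e-6)
  baseline <- spike_nll(Xv, aperm(array(mean_rates,
                                        dim = c(dim(Xv)[3], dim(Xv)[1],
                                                dim(Xv)[2])), c(2, 3, 1)))
  expect_lt(tail(m$log$valid_nll, 1), baseline)
  # the training log matches the metric-suite NLL definition
  inf_tr <- infer(m, gts$dataset, "train")
  expect_equal(spike_nll(gts$X[gts$dataset$train_idx, , , drop = FALSE],
                         inf_tr$rates),
               odinflow:::batch_loss(m, gts$X[gts$dataset$train_idx, , ,
                                              drop = FALSE]) +
                 mean(lgamma(gts$X[gts$dataset$train_idx, , , drop = FALSE] + 1)),
               tolerance = 1e-8)
})

test_that("inference is pure, reproducible and shape-checked", {
  gts <- tiny_benchmark(seed = 17)
  cfg <- tiny_config("flow", epochs = 2, seed = 5)
  m <- train_model(gts$dataset, cfg)
  i1 <- infer(m, gts$dataset, "valid")
  i2 <- infer(m, gts$dataset, "valid")
  expect_identical(i1$Z_hat, i2$Z_hat)
  expect_true(all(i1$rates > 0))
  expect_equal(dim(i1$Z_hat)[3], cfg$D_hat)
  expect_equal(dim(i1$z0_hat), c(length(gts$dataset$valid_idx), cfg$D_hat))
  # first unrolled state is one Euler step from z0
  step1 <- i1$z0_hat + m$config$alpha *
    odinflow:::mlp_forward(m$params$node, i1$z0_hat)
  expect_equal(i1$Z_hat[, 1, ], step1, tolerance = 1e-12, ignore_attr = TRUE)
  # neuron-count mismatch is an error
  bad <- gts$dataset
  bad$X <- bad$X[, , 1:4, drop = FALSE]
  expect_error(infer(m, bad), "neurons")
})

test_that("training is deterministic given the seed", {
  gts <- tiny_benchmark(seed = 19)
  cfg <- tiny_config("mlp", epochs = 3, seed = 8)
  m1 <- train_model(gts$dataset, cfg)
  m2 <- train_model(gts$dataset, cfg)
  expect_equal(m1$params, m2$params, tolerance = 1e-12)
  expect_equal(m1$log, m2$log)
})
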