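linear_dyn <- function(A, z_star) {
  list(f = function(Z) sweep(Z, 2, z_star) %*% t(A),
       jac = function(z) A, D = ncol(A))
}

test_that("a unique linear fixed point is found from any seed", {
  A <- matrix(c(-0.5, 0.2, 0, -0.3), 2, 2)
  z_star <- c(1.5, -2)
  dyn <- linear_dyn(A, z_star)
  set.seed(2)
  seeds <- matrix(rnorm(20, sd = 4), 10, 2)
  fps <- find_fixed_points(dyn, seeds, tol = 1e-10, dedup_radius = 0.1)
  expect_equal(nrow(fps$locations), 1)
  expect_equal(as.numeric(fps$locations), z_star, tolerance = 1e-4)
  expect_lt(fps$residuals[1], 1e-4)
})

test_that("the ground-truth Arneodo map yields exactly the three analytic fixed points", {
  sys <- chaotic_system()
  dyn <- discrete_dynamics(sys)
  truth <- arneodo_fixed_points(sys)
  Z <- integrate_system(sys, 8, 70, seed = 5)
  cands <- fp_candidates(Z, n_seeds = 256, seed = 3)
  fps <- find_fixed_points(dyn, cands, tol = 1e-8)
  expect_equal(nrow(fps$locations), 3)
  found <- fps$locations[order(fps$locations[, 1]), ]
  expect_lt(max(abs(found - truth$locations)), 1e-4)
  # eigenvalues of the one-bin update map (differentiated numerically from
  # the actual integrator, not from the analytic matrix exponential) match
  # the exp(lambda_cont * dt) discretization of the continuous Jacobians
  ord <- order(fps$locations[, 1])
  for (i in 1:3) {
    Jup <- linearize(dyn, fps$locations[ord[i], ], use_finite_diff = TRUE)
    ev_found <- eigen(Jup, only.values = TRUE)$values
    ev_true <- truth$eig_discrete[[i]]
    key <- function(e) e[order(Re(e), Im(e))]
    expect_lt(max(Mod(key(ev_found) - key(ev_true))), 1e-6)
  }
  # central fixed point carries rotational (complex) eigenvalues
  ctr <- which.min(abs(fps$locations[, 1]))
  expect_true(any(abs(Im(fps$eigenvalues[[ctr]])) > 0.01))
})

test_that("linearization is exact for linear dynamics and matches finite differences", {
  A <- matrix(c(-0.4, 0.1, 0.2, -0.6), 2, 2)
  dyn <- linear_dyn(A, c(0, 0))
  J <- linearize(dyn, c(0.3, -0.2))
  expect_equal(J, diag(2) + A, tolerance = 1e-12)
  Jfd <- linearize(dyn, c(0.3, -0.2), use_finite_diff = TRUE)
  expect_equal(Jfd, J, tolerance = 1e-7)
  # analytic MLP Jacobian agrees with finite differences on a trained-style net
  cfg <- tiny_config("linear", seed = 31)
  m <- init_model(cfg, 6)
  m$params$node$W[[2]] <- matrix(rnorm(30, sd = 0.3), 10, 3)
  dyn_m <- model_dynamics(m)
  z <- rnorm(3)
  expect_equal(linearize(dyn_m, z),
               linearize(dyn_m, z, use_finite_diff = TRUE),
               tolerance = 1e-5)
  # symmetric Jacobians give real eigenvalues
  S <- matrix(c(-0.3, 0.1, 0.1, -0.2), 2, 2)
  ev <- eigen(linearize(linear_dyn(S, c(0, 0)), c(0, 0)))$values
  expect_true(all(Im(ev) == 0))
})

test_that("stability classification follows the unit circle", {
  expect_equal(classify_fixed_point(c(0.5, 0.9)), "attractor")
  expect_equal(classify_fixed_point(c(1.1, 0.8)), "saddle")
  expect_equal(classify_fixed_point(complex(real = c(0.9, 0.9),
                                            imaginary = c(0.3, -0.3))),
               "spiral-in")
  expect_equal(classify_fixed_point(complex(real = c(1.2, 1.2),
                                            imaginary = c(0.4, -0.4))),
               "spiral-out")
  expect_equal(classify_fixed_point(c(1.3, 1.7)), "repeller")
  expect_equal(classify_fixed_point(c(1, 0.5)), "center-like")
  expect_error(classify_fixed_point(complex(0)), "empty")
})

test_that("comparison to truth is exact under the identity and affine invariance", {
  sys <- chaotic_system()
  truth <- arneodo_fixed_points(sys)
  fake <- structure(list(locations = truth$locations,
                         residuals = rep(0, 3),
                         jacobians = list(NULL, NULL, NULL),
                         eigenvalues = truth$eig_discrete,
                         labels = rep("saddle", 3)),
                    class = "fixed_point_set")
  id_map <- list(linear = diag(3), offset = rep(0, 3))
  rep0 <- compare_fixed_points(fake, truth$locations, truth$eig_discrete,
                               id_map)
  expect_equal(rep0$matches$location_error, rep(0, 3), tolerance = 1e-12)
  expect_equal(rep0$matches$eig_distance, rep(0, 3), tolerance = 1e-12)
  # model set equal to an affine image of the truth: zero error after transform
  set.seed(8)
  A <- matrix(rnorm(9), 3, 3) + 2 * diag(3)
  b <- rnorm(3)
  mapped <- truth$locations %*% A + matrix(b, 3, 3, byrow = TRUE)
  fake2 <- fake; fake2$locations <- mapped
  rep2 <- compare_fixed_points(fake2, truth$locations, truth$eig_discrete,
                               list(linear = A, offset = b))
  expect_lt(max(rep2$matches$location_error), 1e-10)
  # cardinality mismatch is reported, not fatal
  fake3 <- fake
  fake3$locations <- fake3$locations[1:2, ]
  fake3$eigenvalues <- fake3$eigenvalues[1:2]
  rep3 <- compare_fixed_points(fake3, truth$locations, truth$eig_discrete,
                               id_map)
  expect_equal(rep3$n_model, 2)
  expect_equal(rep3$n_truth, 3)
})

test_that("identically zero dynamics collapse to deduplicated candidates with a warning-free result", {
  dyn0 <- list(f = function(Z) Z * 0, jac = function(z) diag(length(z)) * 0,
               D = 2)
  seeds <- rbind(c(0, 0), c(0.001, 0), c(5, 5))
  fps <- find_fixed_points(dyn0, seeds, tol = 1e-8, dedup_radius = 0.5)
  expect_equal(nrow(fps$locations), 2)
  expect_true(all(fps$residuals < 1e-12))
})
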