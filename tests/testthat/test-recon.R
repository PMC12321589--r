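test_that("single-pixel single-LOR MLEM update has the closed form", {
  # one 1x1 mm pixel, one ray through its centre: a = 1
  m <- system_model(c(1, 1), spacing_mm = 1, n_angles = 1, n_radial_bins = 1,
                    bin_spacing_mm = 1)
  expect_equal(as.numeric(m$A), 1, tolerance = 1e-14)
  y <- sinogram(matrix(5, 1, 1))
  u0 <- image_grid(matrix(1, 1, 1), 1)
  rec <- mlem(y, m, n_iterations = 1, u0 = u0, save_every_iteration = FALSE)
  expect_equal(rec[[1]]$values[1, 1], 5, tolerance = 1e-14)
})

test_that("exact data are a fixed point of the EM update", {
  m <- tiny_model(24, 18)
  u0 <- image_grid(matrix(0, 24, 24), 1.2)
  u0$values[m$cache$fov] <- 1 + 0.3 * sin(seq_len(sum(m$cache$fov)))^2
  y <- forward_project(u0, m)
  rec <- osem(y, m, recon_config(n_subsets = 3, n_iterations = 2,
                                 save_every_iteration = FALSE), u0 = u0)
  expect_equal(rec[[1]]$values, u0$values, tolerance = 1e-12)
})

test_that("single-subset OSEM reproduces the dense textbook MLEM", {
  ph <- tiny_phantom(32, seed = 9)
  m <- system_model(c(32, 32), 1.2, n_angles = 24)
  sim <- simulate_counts(ph$activity, m, 2e5, seed = 10)
  rec <- mlem(sim$y, m, n_iterations = 8, save_every_iteration = FALSE)

  sens <- m$cache$sensitivity
  fov <- m$cache$fov
  u0 <- rep(0, 32 * 32)
  u0[fov] <- sum(sim$y$values) / sum(sens[fov])
  ref <- oracle_mlem_dense(m$A, as.vector(t(sim$y$values)), 8, u0)
  expect_equal(as.vector(rec[[1]]$values), ref, tolerance = 1e-10)
})

test_that("beta = 0 guided reconstruction is identical to OSEM", {
  ph <- tiny_phantom(32, seed = 12)
  m <- system_model(c(32, 32), 1.2, n_angles = 20)
  sim <- simulate_counts(ph$activity, m, 2e5, seed = 13)
  cfg <- recon_config(n_subsets = 5, n_iterations = 3)
  a <- osem(sim$y, m, cfg)
  b <- mrg_reconstruct(sim$y, m, ph$prior, penalty_params(0), cfg)
  for (it in seq_along(a)) expect_identical(a[[it]]$values, b[[it]]$values)
})

test_that("with a constant prior the guided update equals a smoothed-TV-penalized loop", {
  ph <- tiny_phantom(32, seed = 14)
  m <- system_model(c(32, 32), 1.2, n_angles = 20)
  sim <- simulate_counts(ph$activity, m, 2e5, seed = 15)
  flat_prior <- image_grid(matrix(1, 32, 32), 1.2)
  beta <- 1.5; alpha <- 0.01
  cfg <- recon_config(n_subsets = 1, n_iterations = 5)
  rec <- mrg_reconstruct(sim$y, m, flat_prior,
                         penalty_params(beta, alpha = alpha, eta = 1), cfg)

  # independent one-step-late loop with the oracle TV gradient
  sens <- m$cache$sensitivity; fov <- m$cache$fov
  yv <- as.vector(t(sim$y$values))
  u <- matrix(0, 32, 32); u[fov] <- sum(yv) / sum(sens[fov])
  for (it in 1:5) {
    ybar <- as.vector(m$A %*% as.vector(u))
    ratio <- ifelse(ybar > 0, yv / ybar, 0)
    bp <- matrix(as.vector(Matrix::crossprod(m$A, ratio)), 32, 32)
    denom <- sens + beta * oracle_tv_gradient(u, c(1.2, 1.2), alpha)
    denom <- pmax(denom, 1e-3 * sens)
    u[fov] <- u[fov] * bp[fov] / denom[fov]
  }
  expect_equal(rec[[5]]$values, u, tolerance = 1e-10)
})

test_that("objective value follows the Poisson formula and is linear in beta", {
  m <- system_model(c(1, 1), 1, n_angles = 1, n_radial_bins = 1, bin_spacing_mm = 1)
  u1 <- image_grid(matrix(1, 1, 1), 1)
  # single LOR, ybar = 1, y = 1 -> 1 - log 1 = 1
  expect_equal(objective_value(u1, sinogram(matrix(1, 1, 1)), m), 1)
  # y = 0 -> objective = sum(ybar)
  expect_equal(objective_value(u1, sinogram(matrix(0, 1, 1)), m), 1)

  ph <- tiny_phantom(32, seed = 16)
  m2 <- system_model(c(32, 32), 1.2, n_angles = 16)
  sim <- simulate_counts(ph$activity, m2, 1e5, seed = 17)
  rec <- mlem(sim$y, m2, 3, save_every_iteration = FALSE)[[1]]
  # strictly positive reconstruction inside FOV -> finite objective
  xi <- normalized_gradient_field(ph$prior, eta = 0.05)
  o1 <- objective_value(rec, sim$y, m2, xi, penalty_params(1, alpha = 0.01))
  o2 <- objective_value(rec, sim$y, m2, xi, penalty_params(2, alpha = 0.01))
  o0 <- objective_value(rec, sim$y, m2)
  p <- pls_penalty(rec, xi, 0.01)
  expect_equal(o1 - o0, p, tolerance = 1e-8)
  expect_equal(o2 - o1, p, tolerance = 1e-8)
})

test_that("guided objective is non-increasing across full single-subset iterations", {
  ph <- tiny_phantom(32, seed = 18)
  m <- system_model(c(32, 32), 1.2, n_angles = 24)
  sim <- simulate_counts(ph$activity, m, 2e5, seed = 19)
  beta <- 1; alpha <- 0.02; eta <- 0.05
  xi <- normalized_gradient_field(ph$prior, eta)
  rec <- mrg_reconstruct(sim$y, m, ph$prior,
                         penalty_params(beta, alpha = alpha, eta = eta),
                         recon_config(n_subsets = 1, n_iterations = 15))
  obj <- vapply(rec, function(u) {
    objective_value(u, sim$y, m, xi, penalty_params(beta, alpha = alpha, eta = eta))
  }, numeric(1))
  expect_true(all(diff(obj) <= abs(obj[-length(obj)]) * 1e-9))
})

test_that("an oversized penalty triggers the clamp warning", {
  ph <- tiny_phantom(32, seed = 20)
  m <- system_model(c(32, 32), 1.2, n_angles = 16)
  sim <- simulate_counts(ph$activity, m, 1e4, seed = 21)
  expect_warning(
    mrg_reconstruct(sim$y, m, ph$prior, penalty_params(1e7, alpha = 0.01, eta = 0.05),
                    recon_config(n_subsets = 4, n_iterations = 1)),
    "clamp")
})

test_that("grid mismatches and invalid configs are rejected", {
  m <- tiny_model(32, 16)
  y <- sinogram(matrix(1, 16, m$n_radial_bins))
  bad_prior <- image_grid(matrix(1, 8, 8), 1.2)
  expect_error(mrg_reconstruct(y, m, bad_prior, penalty_params(1)), "shape")
  expect_error(recon_config(n_subsets = 0), "n_subsets")
  expect_error(recon_config(n_iterations = 0), "n_iterations")
  expect_error(recon_config(epsilon_floor = 0), "epsilon_floor")
})
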