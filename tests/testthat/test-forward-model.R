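test_that("forward projection is linear and matches the ray-clipping oracle", {
  # 2x2 image, axis-aligned rays through the pixel centres
  m <- system_model(c(2, 2), spacing_mm = 1, n_angles = 2, n_radial_bins = 2,
                    bin_spacing_mm = 1)
  u <- image_grid(matrix(c(1, 2, 3, 4), 2, 2), 1)

  s <- forward_project(u, m)
  for (a in seq_len(m$n_angles)) {
    for (b in seq_len(m$n_radial_bins)) {
      expected <- oracle_project_ray(u$values, 1, 1, m$angles[a], m$offsets[b])
      expect_equal(s$values[a, b], expected, tolerance = 1e-12)
    }
  }

  # zero image -> zero sinogram; scaling -> scaled sinogram
  z <- forward_project(image_grid(matrix(0, 2, 2), 1), m)
  expect_true(all(z$values == 0))
  s3 <- forward_project(image_grid(3.5 * u$values, 1), m)
  expect_equal(s3$values, 3.5 * s$values, tolerance = 1e-12)
})

test_that("projector matches the oracle on oblique rays", {
  set.seed(11)
  n <- 7
  m <- system_model(c(n, n), spacing_mm = 1.3, n_angles = 9, n_radial_bins = 13,
                    bin_spacing_mm = 1.1)
  u <- image_grid(matrix(runif(n * n), n, n), 1.3)
  s <- forward_project(u, m)
  for (a in seq_len(m$n_angles)) {
    for (b in seq_len(m$n_radial_bins)) {
      expected <- oracle_project_ray(u$values, 1.3, 1.3, m$angles[a], m$offsets[b])
      expect_equal(s$values[a, b], expected, tolerance = 1e-10)
    }
  }
})

test_that("back projection is the exact adjoint of forward projection", {
  set.seed(21)
  for (psf in c(0, 2.5)) {
    m <- system_model(c(16, 16), spacing_mm = 1.2, n_angles = 12, psf_fwhm_mm = psf)
    u <- image_grid(matrix(runif(256), 16, 16), 1.2)
    sv <- sinogram(matrix(runif(m$n_angles * m$n_radial_bins),
                          m$n_angles, m$n_radial_bins))
    lhs <- sum(forward_project(u, m)$values * sv$values)
    rhs <- sum(u$values * back_project(sv, m)$values)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  }
  # zero sinogram backprojects to zero
  m <- system_model(c(8, 8), 1, n_angles = 6)
  z <- back_project(sinogram(matrix(0, 6, m$n_radial_bins)), m)
  expect_true(all(z$values == 0))
})

test_that("sensitivity image is strictly positive inside the field of view", {
  m <- tiny_model(32, n_angles = 24)
  sens <- sensitivity_image(m)
  # unit sinogram with unit normalization IS the sensitivity image
  ones <- sinogram(matrix(1, m$n_angles, m$n_radial_bins))
  expect_equal(back_project(ones, m)$values, sens$values, tolerance = 1e-12)
  # central region is comfortably inside the FOV
  expect_true(all(sens$values[8:24, 8:24] > 0))
})

test_that("PSF blur is normalized, flat-preserving and self-adjoint", {
  m <- system_model(c(24, 24), 1.2, n_angles = 16, psf_fwhm_mm = 3)
  flat <- image_grid(matrix(2.5, 24, 24), 1.2)
  gflat <- gaussian_postfilter(flat, 3)
  expect_equal(gflat$values, flat$values, tolerance = 1e-12)

  set.seed(5)
  a <- matrix(runif(24 * 24), 24, 24)
  b <- matrix(runif(24 * 24), 24, 24)
  ga <- gaussian_postfilter(image_grid(a, 1.2), 3)$values
  gb <- gaussian_postfilter(image_grid(b, 1.2), 3)$values
  expect_equal(sum(ga * b), sum(a * gb), tolerance = 1e-10)   # self-adjoint
  expect_equal(sum(ga), sum(a), tolerance = 1e-10)            # sum preserved
  expect_identical(gaussian_postfilter(image_grid(a, 1.2), 0)$values, a)

  # FWHM/sigma relation: impulse response has sd = fwhm / 2.3548 (in mm)
  n <- 41
  imp <- matrix(0, n, n); imp[21, 21] <- 1
  g <- gaussian_postfilter(image_grid(imp, 1), 3)$values
  X2 <- matrix((seq_len(n) - 21)^2, n, n, byrow = TRUE)
  sd_emp <- sqrt(sum(g * X2) / sum(g))
  expect_equal(sd_emp, 3 / (2 * sqrt(2 * log(2))), tolerance = 0.02)
})

test_that("Poisson noise is seeded, integer and mean-correct", {
  m <- tiny_model(32, 16)
  z <- sinogram(matrix(0, 16, m$n_radial_bins))
  expect_true(all(add_poisson_noise(z, 1)$values == 0))

  ybar <- sinogram(matrix(100, 100, 100))
  y1 <- add_poisson_noise(ybar, 42)
  y2 <- add_poisson_noise(ybar, 42)
  expect_identical(y1$values, y2$values)
  expect_true(all(y1$values == round(y1$values)))
  # 4-sigma band on the sample mean of 1e4 Poisson(100) draws
  expect_lt(abs(mean(y1$values) - 100), 4 * sqrt(100 / 1e4))
})

test_that("count thinning matches binomial moments and composes", {
  ybar <- sinogram(matrix(100, 100, 100))
  y <- add_poisson_noise(ybar, 7)
  expect_identical(thin_counts(y, 1, 1)$values, y$values)

  th <- thin_counts(y, 0.125, 8)
  tot <- sum(y$values)
  expect_lt(abs(sum(th$values) - 0.125 * tot), 4 * sqrt(tot * 0.125 * 0.875))
  expect_equal(th$dose_fraction, 0.125)

  # thinning 0.5 twice is distributed as Poisson(0.25 * ybar):
  # compare mean and variance pooled over 100 seeded replicates
  yb <- sinogram(matrix(40, 20, 20))
  pooled <- unlist(lapply(1:100, function(s) {
    y0 <- add_poisson_noise(yb, 1000 + s)
    thin_counts(thin_counts(y0, 0.5, 2000 + s), 0.5, 3000 + s)$values
  }))
  expect_equal(mean(pooled), 10, tolerance = 0.02)
  expect_equal(var(pooled) / mean(pooled), 1, tolerance = 0.05)

  expect_error(thin_counts(y, 0, 1), "fraction")
  expect_error(thin_counts(y, 1.5, 1), "fraction")
  expect_error(thin_counts(sinogram(matrix(0.5, 2, 2)), 0.5, 1), "integer")
})

test_that("shape mismatches are rejected", {
  m <- tiny_model(32, 16)
  expect_error(forward_project(image_grid(matrix(1, 8, 8), 1.2), m), "shape")
  expect_error(back_project(sinogram(matrix(1, 3, 3)), m), "shape")
  expect_error(forward_project(image_grid(matrix(1, 32, 32), 2.0), m), "spacing")
})
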