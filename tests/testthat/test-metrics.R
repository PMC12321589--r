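test_that("roi_stats uses sample SD and exact label selection", {
  u <- image_grid(matrix(c(1, 3, 5, 5, 5, 5), 2, 3), 1)
  rois <- roi_label_map(matrix(c(1L, 1L, 2L, 2L, 2L, 2L), 2, 3),
                        c(A = 1L, B = 2L), 1)
  a <- roi_stats(u, rois, "A")
  expect_equal(a$mean, 2)
  expect_equal(a$sd, sqrt(2))            # sample SD of {1, 3}
  expect_equal(a$max, 3)
  expect_equal(a$n_voxels, 2L)
  b <- roi_stats(u, rois, "B")
  expect_equal(b$sd, 0)
  expect_error(roi_stats(u, rois, "C"), "not present")
})

test_that("CRC, COV, contrasts and CNR follow the printed formulas", {
  st <- function(mean, sd = 0) roi_stats_values(mean = mean, sd = sd)
  expect_equal(crc(st(4), st(1)), 1)
  expect_equal(crc(st(2), st(2)), 0)
  expect_equal(crc(st(2.5), st(1)), 0.5)
  expect_error(crc(st(4), st(0)), "positive")

  expect_equal(roi_cov(st(2, sqrt(2))), sqrt(2) / 2)
  expect_equal(roi_cov(st(5, 0)), 0)

  tc <- tissue_contrasts(st(4), st(1), st(0))
  expect_equal(tc$gm_wm, 4)
  expect_equal(tc$gm_csf, 1)
  tc2 <- tissue_contrasts(st(3), st(2), st(1))
  expect_equal(tc2$gm_wm, 1.5)
  expect_equal(tc2$gm_csf, 2 / 3)
  expect_equal(tissue_contrasts(st(2), st(1), st(2))$gm_csf, 0)

  expect_equal(cnr(st(4), st(1, 0.5)), 6)
  expect_equal(cnr(st(1), st(1, 0.5)), 0)
  expect_equal(cnr(st(4), st(1, 0.25)), 12)   # halving the SD doubles CNR
  expect_error(cnr(st(4), st(1, 0)), "SD")
})

test_that("ratio metrics are invariant under global positive rescaling", {
  set.seed(30)
  for (rep in 1:5) {
    gm <- roi_stats_values(runif(1, 2, 5), runif(1, 0.1, 0.5), runif(1, 5, 6))
    wm <- roi_stats_values(runif(1, 0.5, 2), runif(1, 0.05, 0.3), runif(1, 2, 3))
    csf <- roi_stats_values(runif(1, 0.05, 0.4), runif(1, 0.01, 0.1), runif(1, 0.5, 1))
    c <- runif(1, 0.1, 10)
    sc <- function(s) roi_stats_values(c * s$mean, c * s$sd, c * s$max)
    expect_equal(crc(sc(gm), sc(wm)), crc(gm, wm))
    expect_equal(roi_cov(sc(wm)), roi_cov(wm))
    expect_equal(cnr(sc(gm), sc(wm)), cnr(gm, wm))
    tc1 <- tissue_contrasts(gm, wm, csf); tc2 <- tissue_contrasts(sc(gm), sc(wm), sc(csf))
    expect_equal(tc1$gm_wm, tc2$gm_wm)
    expect_equal(tc1$gm_csf, tc2$gm_csf)
    lr1 <- lesion_ratios(gm, wm); lr2 <- lesion_ratios(sc(gm), sc(wm))
    for (k in c("sbr", "snr", "cbr", "cnr")) expect_equal(lr1[[k]], lr2[[k]])
    sv1 <- suvr_cnr(gm, wm, csf); sv2 <- suvr_cnr(sc(gm), sc(wm), sc(csf))
    expect_equal(sv1$suvr, sv2$suvr)
    expect_equal(sv1$cnr, sv2$cnr)
  }
})

test_that("lesion ratios and SUVR worked examples", {
  lesion <- roi_stats_values(mean = 6, sd = 1, max = 10)
  bg <- roi_stats_values(mean = 2, sd = 0.5, max = 3)
  lr <- lesion_ratios(lesion, bg)
  expect_equal(lr$sbr, 5)
  expect_equal(lr$snr, 20)
  expect_equal(lr$cbr, 2)
  expect_equal(lr$cnr, 8)

  same <- lesion_ratios(roi_stats_values(2, 0.5, 2), bg)
  expect_equal(same$cbr, 0)
  expect_equal(same$cnr, 0)

  # CNR is invariant under adding a constant to both regions
  shift <- function(s, c) roi_stats_values(s$mean + c, s$sd, s$max + c)
  expect_equal(lesion_ratios(shift(lesion, 3), shift(bg, 3))$cnr, lr$cnr)

  expect_equal(suvr_cnr(roi_stats_values(2.4), roi_stats_values(1.2),
                        roi_stats_values(1, 0.25))$suvr, 2)
  expect_equal(suvr_cnr(roi_stats_values(1.2), roi_stats_values(1.2),
                        roi_stats_values(1, 0.25))$suvr, 1)
  expect_equal(suvr_cnr(roi_stats_values(2), roi_stats_values(1),
                        roi_stats_values(1, 0.25))$cnr, 4)
  expect_error(lesion_ratios(lesion, roi_stats_values(0, 0.5)), "background")
  expect_error(suvr_cnr(lesion, roi_stats_values(0), bg), "reference")
})

test_that("edge sharpness is the maximum slope in percent of the profile maximum per mm", {
  prof <- list(positions_mm = 0:4, counts = c(0, 20, 60, 100, 100))
  expect_equal(edge_sharpness(prof), 40)
  ramp <- list(positions_mm = 0:10, counts = 10 * (0:10))
  expect_equal(edge_sharpness(ramp), 10)
  flat <- list(positions_mm = 0:5, counts = rep(3, 6))
  expect_equal(edge_sharpness(flat), 0)
  expect_error(edge_sharpness(list(positions_mm = 0:5, counts = rep(0, 6))), "positive")
  expect_error(edge_sharpness(list(positions_mm = 0:1, counts = 0:1)), "3 samples")
})

test_that("profile extraction interpolates bilinearly and recovers step edges", {
  flat <- image_grid(matrix(4.5, 20, 20), 1)
  pr <- profile_extract(flat, c(2, 2), c(15, 9), 0.5)
  expect_true(all(abs(pr$counts - 4.5) < 1e-12))

  # axis-aligned profile through a vertical step edge
  step <- matrix(0, 20, 20); step[, 11:20] <- 100
  u <- image_grid(step, 1)
  pr2 <- profile_extract(u, c(5, 10), c(15, 10), 1)
  expect_true(all(pr2$counts[1:4] == 0))
  expect_true(all(pr2$counts[8:11] == 100))

  # oblique profile against an independent per-point interpolation oracle
  set.seed(31)
  img <- image_grid(matrix(runif(400), 20, 20), 1.2)
  p0 <- c(3.3, 4.1); p1 <- c(18.7, 15.2)
  pr3 <- profile_extract(img, p0, p1, 0.7)
  L <- sqrt(sum((p1 - p0)^2)); dir <- (p1 - p0) / L
  for (k in seq_along(pr3$positions_mm)) {
    pt <- p0 + pr3$positions_mm[k] * dir
    expect_equal(pr3$counts[k],
                 oracle_bilinear_point(img$values, img$spacing_mm, pt[1], pt[2]),
                 tolerance = 1e-12)
  }

  expect_error(profile_extract(flat, c(2, 2), c(2, 2), 0.5), "degenerate")
  expect_error(profile_extract(flat, c(-5, 2), c(10, 2), 0.5), "inside")
})

test_that("ground-truth phantom metrics are exact", {
  ph <- tiny_phantom(64, seed = 1)
  meas <- place_tissue_rois(ph$rois)
  gm <- roi_stats(ph$activity, meas, "GM")
  wm <- roi_stats(ph$activity, meas, "WM")
  csf <- roi_stats(ph$activity, meas, "CSF")
  expect_equal(crc(gm, wm), 1)
  expect_equal(roi_cov(wm), 0)
  tc <- tissue_contrasts(gm, wm, csf)
  expect_equal(tc$gm_wm, 4)
  expect_equal(tc$gm_csf, 1)
})
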