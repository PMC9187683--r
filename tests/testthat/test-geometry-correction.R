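# Pixel-to-angle mapping, correction-map construction and application.

test_that("pixel viewing angles follow the camera geometry", {
  g <- camera_geometry(c(101, 75), pixel_scale = 2, L = 50)
  # optical-axis target: tank center -> (90, 0)
  v0 <- pixel_to_viewing_angles(51, 38, g)
  expect_equal(v0$theta_cam, 90, tolerance = 1e-10)
  expect_equal(v0$phi_cam, 0, tolerance = 1e-10)
  expect_true(v0$inside)
  # 7 cm below the center at L = 50 cm
  i7 <- 51 + 7 / 0.2
  v7 <- pixel_to_viewing_angles(i7, 38, g)
  expect_equal(v7$theta_cam, 90 + atan(7 / 50) * 180 / pi, tolerance = 1e-10)
  expect_equal(round(v7$theta_cam, 2), 97.97)
  expect_error(pixel_to_viewing_angles(0, 1, g), "outside image")
})

test_that("a 0-17 cm depth span samples roughly 80 to 100 degrees", {
  g <- camera_geometry(c(101, 75), pixel_scale = 2, L = 50)
  v_top <- pixel_to_viewing_angles(51 - 50, 38, g)     # depth 0
  v_deep <- pixel_to_viewing_angles(51 + 35, 38, g)    # depth 17
  expect_equal(v_top$depth, 0, tolerance = 1e-10)
  expect_equal(v_deep$depth, 17, tolerance = 1e-10)
  expect_equal(v_top$theta_cam, 78.69, tolerance = 0.01)
  expect_equal(v_deep$theta_cam, 97.97, tolerance = 0.01)
})

test_that("flat distributions give the identity correction", {
  g <- camera_geometry(c(60, 46), pixel_scale = 4)
  cm <- build_correction_maps(list(flat_distribution()), g, "photon")
  expect_true(all(abs(cm$C_theta - 1) < 1e-12))
  expect_true(all(abs(cm$C_phi - 1) < 1e-12))
  # corrected image equals the raw image for isotropic emission
  img <- matrix(runif(60 * 46), 60, 46)
  corr <- apply_correction(img, cm, g)
  raw <- apply_correction(img, NULL, g)
  expect_equal(corr$dose, raw$dose, tolerance = 1e-12)
})

test_that("halved density at the sampled angles doubles the correction", {
  g <- camera_geometry(c(60, 46), pixel_scale = 4)
  # viewing angles span about 79-101 deg; halve the density in 88-92 deg
  counts <- rep(100, 180)
  counts[89:92] <- 50
  d <- angular_distribution(counts, rep(100, 72),
                            region = list(depth = 10, off_axis = 0, voxel = 1))
  cm <- build_correction_maps(list(d), g, "photon")
  mid <- which.min(abs(cherenkovpol:::pixel_grid(g)$depth - 10))
  edge <- 5
  expect_equal(cm$C_theta[mid, 1] / cm$C_theta[edge, 1], 2, tolerance = 0.05)
})

test_that("correction maps are invariant to histogram rescaling", {
  e6 <- mc_fixture("e6")
  dists <- score_distributions(e6, c(0.5, 1.5, 2.5))
  g <- camera_geometry(c(60, 46), pixel_scale = 4)
  cm1 <- build_correction_maps(dists, g, "electron")
  scaled <- lapply(dists, function(d) {
    d$polar_counts <- d$polar_counts * 7
    d$azimuth_counts <- d$azimuth_counts * 7
    d
  })
  cm2 <- build_correction_maps(scaled, g, "electron")
  expect_equal(cm1$C_theta, cm2$C_theta, tolerance = 1e-12)
  expect_equal(cm1$C_phi, cm2$C_phi, tolerance = 1e-12)
})

test_that("electron corrections vary with depth, photon ones are one map", {
  e6 <- mc_fixture("e6")
  g <- camera_geometry(c(110, 84), pixel_scale = 2)
  dists <- score_distributions(e6, c(0.5, 1.5, 2.5))
  cme <- build_correction_maps(dists, g, "electron")
  # within the electron range the correction changes along depth
  grid <- cherenkovpol:::pixel_grid(g)
  r05 <- which.min(abs(grid$depth - 0.5))
  r25 <- which.min(abs(grid$depth - 2.5))
  expect_gt(abs(cme$C_theta[r05, 1] - cme$C_theta[r25, 1]) /
              cme$C_theta[r25, 1], 0.05)
  # photon mode collapses onto the single central distribution: the map
  # built from several depths equals the map from the central one alone
  p6 <- mc_fixture("p6")
  pd <- score_distributions(p6, c(5, 10, 15))
  cmp_multi <- build_correction_maps(pd, g, "photon")
  cmp_one <- build_correction_maps(pd[2], g, "photon")
  expect_equal(cmp_multi$C_theta, cmp_one$C_theta, tolerance = 1e-12)
})

test_that("applying the correction is pixelwise and linear", {
  g <- camera_geometry(c(40, 30), pixel_scale = 6)
  cm <- build_correction_maps(list(flat_distribution()), g, "photon")
  img <- matrix(runif(1200, 1, 5), 40, 30)
  d1 <- apply_correction(img, cm, g)
  d2 <- apply_correction(2 * img, cm, g)
  expect_equal(d2$dose, 2 * d1$dose, tolerance = 1e-12)
  # out-of-tank pixels are masked
  expect_true(anyNA(d1$dose) ==
                any(!cherenkovpol:::pixel_grid(g)$mask))
})

test_that("mean of the corrections over the field is one", {
  e6 <- mc_fixture("e6")
  dists <- score_distributions(e6, c(0.5, 1.5, 2.5))
  g <- camera_geometry(c(110, 84), pixel_scale = 2)
  cm <- build_correction_maps(dists, g, "electron")
  grid <- cherenkovpol:::pixel_grid(g)
  in_rows <- grid$depth >= 0 & grid$depth <= 20
  in_cols <- abs(grid$lateral) <= 7.5
  # normalization convention: reciprocal densities average to ~1 over the
  # in-tank field (capping of near-zero densities allows a small excess)
  expect_equal(mean(1 / cm$C_theta[in_rows, 1]), 1, tolerance = 0.02)
  expect_equal(mean(1 / cm$C_phi[1, in_cols]), 1, tolerance = 0.02)
})
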