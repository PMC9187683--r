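# Simplified Monte Carlo transport: threshold behaviour, cone-angle oracle,
# Compton kinematics, scoring, and the depth evolution of the distributions.

test_that("electrons below the water threshold emit nothing", {
  ph <- transport_electron(200, seed = 1)     # below 264 keV
  expect_equal(nrow(ph$position), 0)
  ph2 <- transport_electron(263, seed = 1)
  expect_equal(nrow(ph2$position), 0)
})

test_that("without scattering every photon sits on the analytic cone", {
  set.seed(12)
  ph <- transport_electron(6000, scattering = FALSE)
  expect_gt(nrow(ph$position), 100)
  polar <- acos(ph$direction[, 3]) * 180 / pi
  expected <- cherenkov_angle(beta_from_kinetic_energy(ph$energy_kev), 1.33)
  expect_lt(max(abs(polar - expected)), 1e-9)
  # energy bookkeeping: no photon generated below threshold
  expect_true(all(ph$energy_kev > cherenkov_threshold_energy(1.33)))
  # polarization transverse and unit-norm
  expect_lt(max(abs(rowSums(ph$polarization * ph$direction))), 1e-12)
  expect_equal(rowSums(ph$polarization^2), rep(1, nrow(ph$position)),
               tolerance = 1e-12)
})

test_that("transport is deterministic given a seed and scales with primaries", {
  a <- transport_electron(6000, seed = 42)
  b <- transport_electron(6000, seed = 42)
  expect_identical(a, b)
  set.seed(9); n1 <- nrow(cherenkovpol:::bind_photons(
    lapply(1:20, function(k) transport_electron(6000)))$position)
  set.seed(9); n2 <- nrow(cherenkovpol:::bind_photons(
    lapply(1:80, function(k) transport_electron(6000)))$position)
  # linear scaling within a few sqrt(N)
  expect_lt(abs(n2 - 4 * n1) / (4 * n1), 0.1)
})

test_that("18 MeV shallow polar histogram peaks in the 41-degree bin", {
  ph <- mc_fixture("e18_shallow")
  d <- score_distributions(ph, list(list(depth = 0.5, off_axis = 0)))[[1]]
  expect_gt(d$n_photons, 1e4)
  expect_equal(polar_mode(d), 41)
  # analytic oracle: the cone angle at 18 MeV is inside the argmax bin
  ang <- cherenkov_angle(beta_from_kinetic_energy(18000), 1.33)
  expect_lt(abs(polar_mode(d) + 0.5 - ang), 1.0)
})

test_that("halving the step does not move the shallow polar mode bin", {
  set.seed(55)
  ph_h <- cherenkovpol:::bind_photons(
    lapply(1:60, function(k) transport_electron(18000, step_cm = 0.05)))
  d_h <- score_distributions(ph_h, list(list(depth = 0.5, off_axis = 0)))[[1]]
  expect_equal(polar_mode(d_h), 41)
})

test_that("Compton electron energies respect the kinematic maximum", {
  set.seed(31)
  for (E in c(1000, 2000, 5000)) {
    alpha <- E / 510.99895
    xs <- vapply(1:2000, function(k) cherenkovpol:::sample_kahn(alpha),
                 numeric(1))
    T_e <- E * (1 - 1 / xs)
    expect_true(all(T_e <= E * 2 * alpha / (1 + 2 * alpha) + 1e-9))
    expect_true(all(T_e >= 0))
  }
})

test_that("photon interaction depths reproduce the attenuation length", {
  set.seed(17)
  mu <- water_attenuation(2000)            # 1/mu = 20.2 cm at 2 MeV
  big_tank <- c(1000, 1000, 1e4)
  depths <- vapply(1:400, function(k) {
    ph <- transport_photon_primary(2000, tank = big_tank)
    if (nrow(ph$position) == 0) NA_real_ else min(ph$position[, 3])
  }, numeric(1))
  depths <- depths[!is.na(depths)]
  expect_gt(length(depths), 300)
  # photon production starts at the interaction point, so the per-primary
  # minimum depth estimates the sampled exponential's mean
  expect_lt(abs(mean(depths) - 1 / mu) / (1 / mu), 0.15)
})

test_that("scoring conserves counts and sees cylindrical symmetry on axis", {
  set.seed(23)
  ph <- cherenkovpol:::bind_photons(
    lapply(1:40, function(k) transport_electron(18000)))
  d <- score_distributions(ph, list(list(depth = 0.5, off_axis = 0)),
                           camera_side_filter = FALSE)[[1]]
  expect_equal(sum(d$polar_counts), d$n_photons)
  expect_equal(sum(d$azimuth_counts), d$n_photons)
  # pencil beam on axis: azimuth uniform (chi-squared GOF at alpha = 0.01)
  exp_counts <- rep(d$n_photons / length(d$azimuth_counts),
                    length(d$azimuth_counts))
  chi2 <- sum((d$azimuth_counts - exp_counts)^2 / exp_counts)
  dof <- length(d$azimuth_counts) - 1
  expect_lt(chi2, qchisq(0.99, dof))
  # camera-side filter keeps only photons heading toward the camera
  d_f <- score_distributions(ph, list(list(depth = 0.5, off_axis = 0)))[[1]]
  expect_lt(d_f$n_photons, d$n_photons)
})

test_that("empty scoring regions are flagged", {
  ph <- transport_electron(1000, seed = 2)
  d <- score_distributions(ph, list(list(depth = 19.5, off_axis = 7)))[[1]]
  expect_equal(d$n_photons, 0)
  expect_true(isTRUE(attr(d, "empty")))
})

test_that("electron distributions evolve with depth, photon ones do not", {
  e6 <- mc_fixture("e6")
  # 5-degree bins keep the comparison robust at these photon counts
  de <- score_distributions(e6, c(0.5, 2.5), polar_bin = 5,
                            camera_side_filter = FALSE)
  p6 <- mc_fixture("p6")
  dp <- score_distributions(p6, c(5, 12), polar_bin = 5,
                            camera_side_filter = FALSE)
  tv <- function(a, b) {
    pa <- cherenkovpol:::polar_density(a)$density
    pb <- cherenkovpol:::polar_density(b)$density
    sum(abs(pa - pb)) * 5 / 2      # total-variation distance
  }
  mean_polar <- function(d) {
    pd <- cherenkovpol:::polar_density(d)
    sum(pd$centers * pd$density) * 5
  }
  # electron distributions broaden and shift toward larger polar angles
  # with depth (scattering isotropizes the electron fluence)
  expect_gt(mean_polar(de[[2]]), mean_polar(de[[1]]) + 5)
  # beyond d_max, photon-beam distributions stay mutually consistent while
  # electron-beam distributions keep evolving
  expect_lt(tv(dp[[1]], dp[[2]]), tv(de[[1]], de[[2]]))
})

test_that("off-axis electron regions develop azimuthal asymmetry", {
  e6 <- mc_fixture("e6")
  mean_dx <- vapply(c(0, 1.5, 2.8), function(off) {
    sel <- abs(e6$position[, 3] - 1.5) <= 0.5 &
      abs(e6$position[, 1] - off) <= 0.5 & abs(e6$position[, 2]) <= 0.5
    mean(e6$direction[sel, 1])
  }, numeric(1))
  # photons increasingly lean outward (+x) as the region approaches the
  # field edge, where electronic equilibrium is lost; photons from one
  # electron are correlated, so the on-axis mean has a cluster-level noise
  # floor of a few hundredths
  expect_lt(abs(mean_dx[1]), 0.1)
  expect_gt(mean_dx[3], mean_dx[1] + 0.15)
  expect_gt(mean_dx[3], 0.15)
})
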