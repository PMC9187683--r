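# Malus decomposition: closed-form four-angle solver, general fit,
# DoLP/AoLP maps and region statistics.

test_that("Malus forward model evaluates correctly", {
  expect_equal(malus_intensity(2, 1, 0, 0), 3)
  expect_equal(malus_intensity(2, 1, 90, 0), 1)
  expect_equal(malus_intensity(2, 1, 45, 0), 2)
  expect_equal(malus_intensity(2, 1, 180, 0), 3)   # 180-degree period
  expect_error(malus_intensity(-1, 0, 0, 0), ">= 0")
})

test_that("four-angle closed form solves model data exactly", {
  s <- model_stack(2, 1, 0, dims = c(2, 2))   # I = [3, 2, 1, 2]
  m <- solve_four_angles(s)
  expect_equal(m$I_pol[1, 1], 2, tolerance = 1e-12)
  expect_equal(m$I_unpol[1, 1], 1, tolerance = 1e-12)
  expect_equal(m$aolp[1, 1], 0, tolerance = 1e-10)
  expect_equal(m$dolp[1, 1], 100 * 2 / 3, tolerance = 1e-12)
  expect_true(all(m$fit_residual < 1e-12))
})

test_that("unpolarized and fully polarized limits are exact", {
  eq <- model_stack(0, 5, 0)
  m_eq <- solve_four_angles(eq)
  expect_true(all(m_eq$dolp == 0))
  expect_true(all(is.na(m_eq$aolp)))       # AoLP undefined without signal
  pure <- model_stack(1, 0, 45)
  m_p <- solve_four_angles(pure)
  expect_true(all(abs(m_p$dolp - 100) < 1e-10))
  expect_true(all(abs(m_p$aolp - 45) < 1e-10))
})

test_that("noiseless round trip recovers generating fields", {
  fl <- random_fields(dims = c(6, 5), seed = 3)
  s <- model_stack(fl$I_pol, fl$I_unpol, fl$alpha)
  m <- solve_four_angles(s)
  expect_equal(m$I_pol, fl$I_pol, tolerance = 1e-10)
  expect_equal(m$I_unpol, fl$I_unpol, tolerance = 1e-10)
  expect_equal(m$aolp, fl$alpha, tolerance = 1e-8)
  expect_true(all(m$dolp >= 0 & m$dolp <= 100))
})

test_that("AoLP is equivariant under rotation of the generating angle", {
  fl <- random_fields(dims = c(4, 4), seed = 9)
  base <- solve_four_angles(model_stack(fl$I_pol, fl$I_unpol, fl$alpha))
  for (delta in c(10, -25, 60)) {
    shifted <- solve_four_angles(
      model_stack(fl$I_pol, fl$I_unpol, fl$alpha + delta))
    dd <- (shifted$aolp - base$aolp - delta) %% 180
    dd <- pmin(dd, 180 - dd)
    expect_true(all(dd < 1e-8))
    expect_equal(shifted$dolp, base$dolp, tolerance = 1e-10)
  }
})

test_that("orthogonal-pair sums agree on model data and flag noise", {
  fl <- random_fields(dims = c(5, 5), seed = 21)
  s <- model_stack(fl$I_pol, fl$I_unpol, fl$alpha)
  # I(0) + I(90) = I(45) + I(135) exactly for model data
  expect_equal(s$frames[["0"]] + s$frames[["90"]],
               s$frames[["45"]] + s$frames[["135"]], tolerance = 1e-12)
  expect_true(all(solve_four_angles(s)$fit_residual < 1e-10))
  # perturbing one frame shows up in the residual of that pixel
  noisy <- s
  noisy$frames[["45"]][2, 3] <- noisy$frames[["45"]][2, 3] + 0.5
  r <- solve_four_angles(noisy)$fit_residual
  expect_gt(r[2, 3], 0.4)
  expect_lt(max(r[-(2 + (3 - 1) * 5)]), 1e-10)
})

test_that("general fit recovers parameters from arbitrary angle sets", {
  ang5 <- c(0, 36, 72, 108, 144)
  y <- malus_intensity(2.5, 0.7, ang5, 25)
  f <- fit_general(ang5, y)
  expect_equal(f$I_pol, 2.5, tolerance = 1e-8)
  expect_equal(f$I_unpol, 0.7, tolerance = 1e-8)
  expect_equal(f$alpha, 25, tolerance = 1e-8)
  # agreement with the closed form on random noiseless 4-angle data
  set.seed(5)
  for (rep in 1:10) {
    Ip <- runif(1, 0.1, 4); Iu <- runif(1, 0, 2); al <- runif(1, -89, 89)
    ang <- c(0, 45, 90, 135)
    f4 <- fit_general(ang, malus_intensity(Ip, Iu, ang, al))
    m <- solve_four_angles(model_stack(Ip, Iu, al, dims = c(1, 1)))
    expect_equal(f4$I_pol, m$I_pol[1, 1], tolerance = 1e-8)
    expect_equal(f4$I_unpol, m$I_unpol[1, 1], tolerance = 1e-8)
  }
  # constant data: no polarized amplitude, masked angle
  fc <- fit_general(ang5, rep(2, 5))
  expect_equal(fc$I_pol, 0, tolerance = 1e-8)
  expect_true(is.na(fc$alpha))
  expect_error(fit_general(c(0, 90), c(1, 2)), "underdetermined")
})

test_that("non-standard angle stacks fall back to the general fit", {
  angles <- c(0, 60, 120)
  frames <- lapply(angles, function(a0)
    matrix(malus_intensity(3, 1, a0, 20), 3, 3))
  names(frames) <- as.character(angles)
  m <- solve_four_angles(polarized_stack(frames))
  expect_equal(m$I_pol[2, 2], 3, tolerance = 1e-6)
  expect_equal(m$aolp[2, 2], 20, tolerance = 1e-6)
})

test_that("negative DC from noise is clamped and flagged", {
  # a stack where I(0) + I(90) < I_pol forces a negative fitted DC
  frames <- list("0" = matrix(1, 2, 2), "45" = matrix(0.5, 2, 2),
                 "90" = matrix(0, 2, 2), "135" = matrix(0.4, 2, 2))
  m <- solve_four_angles(polarized_stack(frames))
  expect_true(all(m$qa_mask))
  expect_true(all(m$I_unpol == 0))
  expect_true(all(m$dolp == 100))
})

test_that("region DoLP statistics behave analytically", {
  m <- solve_four_angles(model_stack(1, 1, 10, dims = c(6, 6)))
  st <- region_dolp_stats(m, list(rows = 2:5, cols = 2:5))
  expect_equal(unname(st["mean"]), 50, tolerance = 1e-10)
  expect_equal(unname(st["sd"]), 0, tolerance = 1e-10)
  # two-valued field: analytic mean and sd
  Ip <- matrix(c(1, 3), 2, 2)           # DoLP 50 and 75 alternating rows
  m2 <- solve_four_angles(model_stack(Ip, 1, 0, dims = c(2, 2)))
  st2 <- region_dolp_stats(m2, list(rows = 1:2, cols = 1:2))
  expect_equal(unname(st2["mean"]), mean(c(50, 75, 50, 75)))
  expect_equal(unname(st2["sd"]), sd(c(50, 75, 50, 75)))
  expect_error(region_dolp_stats(m, list(rows = 9:10, cols = 1:2)),
               "outside")
})

test_that("Poisson noise on an unpolarized stack leaves a small positive bias", {
  set.seed(77)
  counts <- 1e4
  means <- vapply(1:15, function(k) {
    frames <- lapply(c(0, 45, 90, 135), function(a)
      matrix(rpois(400, counts), 20, 20))
    names(frames) <- c("0", "45", "90", "135")
    unname(region_dolp_stats(solve_four_angles(polarized_stack(frames)),
                             list(rows = 1:20, cols = 1:20))["mean"])
  }, numeric(1))
  expect_gt(mean(means), 0)       # Rayleigh-floor bias is positive
  expect_lt(mean(means), 2)       # but small at 1e4 counts/pixel
})
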