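test_that("sphericity is calibrated on a voxelized ball", {
  b <- ball_mask(20)
  expect_equal(sphericity(b), 1.00, tolerance = 0.03)
  # analytic area oracle: mesh area within a few percent of 4*pi*r^2
  expect_equal(mask_surface_area(b), 4 * pi * 20^2, tolerance = 0.03)
})

test_that("sphericity of a cube approaches (pi/6)^(1/3) at adequate resolution", {
  # edge rounding by the sub-voxel smoothing is O(sigma/side), so the
  # estimate converges to the closed form as the cube grows
  cu <- cube_mask(120)
  expect_equal(sphericity(cu), (pi / 6)^(1 / 3), tolerance = 0.02)
})

test_that("spiculations strictly lower sphericity for every seed", {
  for (seed in 1:10) {
    plain <- generate_phantom(phantom_spec(shape = c(40L, 40L, 40L), base_radius = 8,
                                           scan_times = 0, seed = seed))
    spic <- generate_phantom(phantom_spec(shape = c(40L, 40L, 40L), base_radius = 8,
                                          scan_times = 0, n_spiculations = 8L,
                                          spiculation_length = 6, seed = seed))
    expect_lt(sphericity(spic$scans[[1]]$mask), sphericity(plain$scans[[1]]$mask))
  }
})

test_that("sphericity is invariant to isotropic rescaling of the same ball", {
  vals <- c(sphericity(ball_mask(8, 25, c(1, 1, 1))),
            sphericity(ball_mask(8, 33, c(0.8, 0.8, 0.8))),
            sphericity(ball_mask(8, 41, c(0.5, 0.5, 0.5))))
  expect_lt(max(vals) - min(vals), 0.03)
})

test_that("PD-L1 area ratio counts overlap fractions", {
  tum <- ball_mask(5, 16)
  expect_equal(pdl1_area_ratio(tum, tum), 1)
  none <- seg_mask(array(0L, dim(tum$voxels)), tum$spacing)
  expect_equal(pdl1_area_ratio(tum, none), 0)
  # half-overlap construction: positive region = half-space through center
  half <- tum
  half$voxels[1:8, , ] <- 0L
  r <- pdl1_area_ratio(tum, half)
  expect_equal(r, sum(half$voxels) / sum(tum$voxels), tolerance = 1e-12)
  expect_equal(r, 0.5, tolerance = 0.1)
  expect_error(pdl1_area_ratio(none, tum), class = "mkunet_validation_error")
})

test_that("IES reproduces its published component weights", {
  expect_identical(ies(1, 1, 0), 0.6)
  expect_identical(ies(0, 0, 0), 0.3)
  expect_identical(ies(0, 1, 1), 0.1)
  w <- ies_weights()
  expect_equal(ies(1, 0, 1), w$w_lvcr + w$w_shape + w$w_pdl1)
})

test_that("IES is monotone in each component", {
  set.seed(55)
  for (i in 1:20) {
    l <- runif(1); s <- runif(1); p <- runif(1); d <- runif(1, 0.01, 0.5)
    expect_gt(ies(l + d, s, p), ies(l, s, p))
    expect_lt(ies(l, s + d, p), ies(l, s, p))
    expect_gt(ies(l, s, p + d), ies(l, s, p))
  }
})

test_that("IES pipeline: spherical no-growth limit, determinism, monotonicity", {
  static <- generate_phantom(phantom_spec(shape = c(40L, 40L, 40L), base_radius = 9,
                                          growth_rate = 0, scan_times = c(0, 10, 20),
                                          seed = 2))
  s_static <- phantom_series_volumes(static)
  r1 <- ies_pipeline(s_static, static$scans[[3]]$mask)
  # zero growth maps to normalize_lvcr(0) ~ 0.143; the shape term vanishes
  # within mesh tolerance and PD-L1 defaults to 0 with a missing flag
  expect_true(r1$pdl1_missing)
  expect_equal(r1$pdl1_ratio, 0)
  expect_equal(abs(1 - r1$sphericity), 0, tolerance = 0.05)
  expect_lt(abs(r1$ies - 0.6 * normalize_lvcr(0)), 0.02)
  r2 <- ies_pipeline(s_static, static$scans[[3]]$mask)
  expect_identical(r1$ies, r2$ies)

  growing <- generate_phantom(phantom_spec(shape = c(48L, 48L, 48L), base_radius = 9,
                                           growth_rate = 0.2, scan_times = c(0, 5, 10),
                                           n_spiculations = 8L, spiculation_length = 5,
                                           seed = 2))
  s_grow <- phantom_series_volumes(growing)
  r3 <- ies_pipeline(s_grow, growing$scans[[3]]$mask)
  expect_gt(r3$ies, r1$ies)
  expect_identical(r3$stratum, "high")
  expect_identical(r1$stratum, "low")
  # raw mode reports the slope itself as the growth component
  r4 <- ies_pipeline(s_grow, growing$scans[[3]]$mask, lvcr_mode = "raw")
  expect_equal(r4$lvcr_score, r4$lvcr)
})
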