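test_that("analytic region volumes follow from the sphere and cylinder dimensions", {
  ph <- buildJaszczak(gridSpec(c(32L, 32L, 32L), 8))
  rt <- regionTable(ph)
  d <- c(9.9, 12.4, 15.4, 19.8, 24.8, 31.3)
  # independent closed-form volumes
  expect_equal(sort(rt$analyticVolume_ml[rt$label %in% 2:7]),
               sort(pi / 6 * d^3 / 1000), tolerance = 1e-12)
  expect_equal(sum(rt$analyticVolume_ml[rt$label %in% 2:7]), 31.525,
               tolerance = 1e-3)
  # uniform cylinder: background analytic volume = pi R^2 H
  phu <- buildJaszczak(gridSpec(c(32L, 32L, 32L), 8), spheres = NULL,
                       backgroundConc = 0.05)
  expect_equal(regionTable(phu)$analyticVolume_ml[1],
               pi * 103^2 * 186 / 1000, tolerance = 1e-12)
})

test_that("uniform cylinder assigns the background concentration to every interior voxel", {
  ph <- buildJaszczak(gridSpec(c(32L, 32L, 32L), 8), spheres = NULL,
                      backgroundConc = 0.07)
  a <- activityMap(ph)
  lab <- regionLabels(ph)
  expect_true(all(a[lab == 1L] == 0.07))
  expect_true(all(a[lab != 1L] == 0))
})

test_that("geometry violations are rejected", {
  g <- gridSpec(c(32L, 32L, 32L), 8)
  outside <- sphereSpec(c(100, 0, 0), 31.3, 2, 1)
  expect_error(buildJaszczak(g, outside), "outside")
  overlapping <- rbind(sphereSpec(c(0, 0, 0), 31.3, 2, 1),
                       sphereSpec(c(10, 0, 0), 19.8, 2, 1))
  expect_error(buildJaszczak(g, overlapping), "overlap")
})

test_that("voxelized volumes converge to the analytic volumes under grid refinement", {
  sp <- rbind(sphereSpec(c(18, 0, 0), 31.3, 2, 1),
              sphereSpec(c(-20, 0, 0), 19.8, 2, 1))
  err <- sapply(c(2, 1), function(v) {
    n <- as.integer(round(96 / v))
    ph <- buildJaszczak(gridSpec(c(n, n, as.integer(round(80 / v))), v), sp,
                        backgroundConc = 0.05, innerDiameter = 80,
                        innerHeight = 60, wallThickness = 7)
    rt <- regionTable(ph)
    abs(rt$voxelVolume_ml - rt$analyticVolume_ml) / rt$analyticVolume_ml
  })
  # rows: background, sphere 31.3, sphere 19.8, wall; cols: 2 mm, 1 mm;
  # voxel-centre volume error is oscillatory, so only the refined bound is
  # asserted, for every region
  expect_lt(max(err[, 2]), 0.02)
})

test_that("total phantom activity equals the per-region concentration x voxelized volume", {
  ph <- buildJaszczak(gridSpec(c(48L, 48L, 48L), 6))
  rt <- regionTable(ph)
  expect_equal(sum(activityMap(ph)) * voxelVolume(ph),
               sum(rt$conc_MBq_ml * rt$voxelVolume_ml), tolerance = 1e-12)
})

test_that("decay follows the half-life and is multiplicative", {
  expect_equal(decayActivity(341, 26.8), 170.5)
  expect_equal(decayActivity(123.4, 0), 123.4)
  # numerically invert the decay for the activity at the last acquisition
  el <- uniroot(function(t) decayActivity(341, t) - 321.5, c(0, 20),
                tol = 1e-10)$root
  expect_equal(el, 2.2767, tolerance = 1e-4)
  expect_equal(decayActivity(341, el), 321.5, tolerance = 1e-8)
  set.seed(5)
  for (i in 1:20) {
    t1 <- runif(1, 0, 50); t2 <- runif(1, 0, 50)
    expect_equal(decayActivity(100, t1 + t2),
                 decayActivity(decayActivity(100, t1), t2),
                 tolerance = 1e-12)
  }
  expect_error(decayActivity(100, -1), "elapsed")
})

test_that("attenuation map interpolates standard tables and zeroes air", {
  ph <- buildJaszczak(gridSpec(c(32L, 32L, 32L), 8))
  mu <- attenuationMap(ph, 80.6)
  lab <- regionLabels(ph)
  expect_true(all(mu[lab == 0L] == 0))
  expect_equal(unique(mu[lab == 1L]), 0.1833, tolerance = 0.005)
  # wall is denser than water at this energy
  expect_gt(unique(mu[lab == 8L]), unique(mu[lab == 1L]))
  # monotone decrease of water attenuation with energy
  mu60 <- attenuationMap(ph, 60); mu100 <- attenuationMap(ph, 100)
  expect_gt(unique(mu60[lab == 1L]), unique(mu100[lab == 1L]))
  expect_error(attenuationMap(ph, 200), "range")
})
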