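test_that("local-deposition dose map matches closed forms and conserves energy", {
  dp <- doseParams(administeredActivity = 2, doseCoefficient = 15.87)
  # all activity in one voxel of mass m
  v <- array(0, c(3, 3, 3)); v[2, 2, 2] <- 7
  d <- lddDoseMap(v, dp, voxelMass = 0.5)
  expect_equal(d[2, 2, 2], 2 * 15.87 * 1000 / 0.5)
  expect_true(all(d[-14] == 0))
  # energy conservation: sum(dose * mass) = A * kappa (J -> Gy bookkeeping)
  set.seed(8)
  v2 <- array(runif(64), c(4, 4, 4))
  m2 <- array(runif(64, 0.5, 2), c(4, 4, 4))
  d2 <- lddDoseMap(v2, dp, voxelMass = m2)
  expect_equal(sum(d2 * m2 / 1000), 2 * 15.87, tolerance = 1e-9)
  # 2-voxel toy: counts 3:1, masses 2:1 -> doses 3:2
  v3 <- array(c(3, 1), c(2, 1, 1)); m3 <- array(c(2, 1), c(2, 1, 1))
  d3 <- lddDoseMap(v3, doseParams(1, 10), voxelMass = m3)
  expect_equal(d3[1] / d3[2], 3 / 2, tolerance = 1e-12)
  expect_equal(d3[1], 1 * 10 * (3 / 4) * 1000 / 2, tolerance = 1e-12)
  # linearity in administered activity
  dA <- lddDoseMap(v2, doseParams(4, 15.87), voxelMass = m2)
  expect_equal(dA, 2 * d2, tolerance = 1e-12)
  expect_error(lddDoseMap(array(0, c(2, 1, 1)), dp, voxelMass = 1), "zero total")
  expect_error(lddDoseMap(array(-1, c(2, 1, 1)), dp, voxelMass = 1),
               "negative")
})

test_that("compartment fractions follow the 150 Gy and 0-50 Gy criteria", {
  tumor <- array(FALSE, c(10, 1, 1)); tumor[1:5, 1, 1] <- TRUE
  ntl <- array(FALSE, c(10, 1, 1)); ntl[6:10, 1, 1] <- TRUE
  d <- array(c(200, 200, 200, 200, 200, 60, 60, 60, 60, 60), c(10, 1, 1))
  rep1 <- compartmentStats(d, tumor, ntl)
  s <- doseSummary(rep1)
  expect_equal(s$fraction_ge_150Gy[s$compartment == "tumor"], 1)
  expect_equal(s$fraction_0_50Gy[s$compartment == "ntl"], 0)
  # enumerated toy: exact boundary handling (>= 150 in; 50 excluded from 0-50)
  d2 <- array(c(150, 149.9, 10, 300, 80, 0, 49.99, 50, 120, 30), c(10, 1, 1))
  s2 <- doseSummary(compartmentStats(d2, tumor, ntl))
  expect_equal(s2$fraction_ge_150Gy[s2$compartment == "tumor"], 2 / 5)
  expect_equal(s2$fraction_0_50Gy[s2$compartment == "ntl"], 3 / 5)
  # mass-weighted mean equals energy / compartment mass (two routes)
  m <- array(runif(10, 0.5, 2), c(10, 1, 1))
  s3 <- doseSummary(compartmentStats(d2, tumor, ntl, voxelMass = m))
  expect_equal(s3$meanDose_Gy[1], sum(d2[tumor] * m[tumor]) / sum(m[tumor]),
               tolerance = 1e-12)
  expect_error(compartmentStats(d2, tumor, tumor), "overlap")
  expect_error(compartmentStats(d2, array(FALSE, c(10, 1, 1)), ntl), "empty")
})

test_that("activity planning is linear with lung-dose constraint flags", {
  p <- planActivity(20, 200)
  expect_equal(p$planned_GBq, 10)
  expect_true(p$feasible)
  v <- planActivity(20, 200, lungDosePerUnit = 4)
  expect_equal(v$lungDose_Gy, 40)
  expect_false(v$lungSingleOK)
  expect_false(v$feasible)
  # cumulative limit over multiple treatments
  c2 <- planActivity(20, 200, lungDosePerUnit = 2.5, priorLungDose = 30)
  expect_true(c2$lungSingleOK)
  expect_false(c2$lungCumulativeOK)
  # target range endpoints give proportional activities
  lo <- planActivity(20, 169); hi <- planActivity(20, 300)
  expect_equal(hi$planned_GBq / lo$planned_GBq, 300 / 169, tolerance = 1e-12)
  expect_error(planActivity(0, 200), "dosePerUnitActivity")
})

test_that("paired t-test matches the closed form and a quadrature oracle", {
  x <- c(201.9, 178.9, 229.4, 168.3, 190.0)
  y <- c(196.2, 180.1, 214.8, 160.9, 192.4)
  tt <- pairedTTest(x, y)
  d <- x - y
  tHand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(tt$t, tHand, tolerance = 1e-12)
  expect_identical(tt$df, 4L)
  # two-sided p by numerical integration of the t density
  dens <- function(u, df) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + u^2 / df)^(-(df + 1) / 2)
  pQuad <- 2 * integrate(dens, abs(tHand), Inf, df = 4,
                         rel.tol = 1e-12)$value
  expect_equal(tt$p, pQuad, tolerance = 1e-9)
  # cross-check against the reference implementation
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-12)
  # symmetry and degenerate cases
  flip <- pairedTTest(y, x)
  expect_equal(flip$t, -tt$t, tolerance = 1e-12)
  expect_equal(flip$p, tt$p, tolerance = 1e-12)
  same <- pairedTTest(x, x)
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_false(same$significant)
  expect_error(pairedTTest(1, 2), "2 pairs")
  expect_error(pairedTTest(c(1, 2), c(0, 1)), "zero variance")
})
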