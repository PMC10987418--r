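test_that("window bounds reproduce the acquisition window table", {
  expect_equal(unname(windowBounds(80.6, 15.0)), c(74.56, 86.65),
               tolerance = 1e-4)
  expect_equal(unname(windowBounds(71.56, 8.39)), c(68.56, 74.56),
               tolerance = 1e-4)
  expect_equal(unname(windowBounds(89.65, 6.69)), c(86.65, 92.65),
               tolerance = 1e-4)
  # console prints 112.0/124.0; exact arithmetic is within display rounding
  b4 <- windowBounds(118.0, 10.2)
  expect_lt(max(abs(b4 - c(112.0, 124.0))), 0.05)
  expect_equal(unname(windowBounds(50, 0)), c(50, 50))
  wt <- defaultWindows()
  expect_identical(wt$label, c("W1", "W2", "W3", "W4"))
  expect_equal(wt$width[wt$label %in% c("W1", "W3")], c(6, 6),
               tolerance = 1e-3)
  expect_equal(wt$width[wt$label == "W2"], 12.09, tolerance = 1e-3)
})

test_that("DEW correction is exact elementwise subtraction with scaling", {
  set.seed(42)
  p2 <- array(rpois(27, 50), c(3, 3, 3))
  p4 <- array(rpois(27, 20), c(3, 3, 3))
  expect_identical(dewCorrect(p2, p4, dewParams(0)), p2 * 1)
  expect_true(all(dewCorrect(p2, p2, dewParams(1)) == 0))
  # brute-force elementwise oracle, no clamping
  k <- 1
  out <- dewCorrect(p2, p4, dewParams(k), clamp = FALSE)
  for (i in seq_along(out)) expect_identical(out[i], p2[i] - k * p4[i])
  expect_error(dewCorrect(p2, array(0, c(2, 2, 2))), "mismatch")
})

test_that("TEW trapezoid reduces to direct subtraction at the protocol widths", {
  set.seed(43)
  p2 <- array(rpois(200, 100), c(10, 5, 4))
  p1 <- array(rpois(200, 30), c(10, 5, 4))
  p3 <- array(rpois(200, 25), c(10, 5, 4))
  tew <- tewCorrect(p2, p1, p3, widths = c(6, 12, 6), clamp = TRUE)
  direct <- pmax(p2 - combineSideWindows(p1, p3), 0)
  expect_identical(tew, direct)
  # general trapezoid against the hand formula
  out <- tewCorrect(p2, p1, p3, widths = c(4, 12, 8), clamp = FALSE)
  expect_equal(out, p2 - (p1 / 4 + p3 / 8) * 12 / 2, tolerance = 1e-15)
  # zero side windows: identity
  z <- array(0, dim(p2))
  expect_equal(tewCorrect(p2, z, z), p2 * 1)
  expect_error(tewCorrect(p2, p1, p3, widths = c(0, 12, 6)), "widths")
  expect_error(tewCorrect(p2, p1, array(0, c(2, 2, 2))), "mismatch")
})

test_that("side-window combination is the elementwise sum", {
  set.seed(44)
  a <- array(runif(60), c(5, 4, 3))
  b <- array(runif(60), c(5, 4, 3))
  expect_identical(combineSideWindows(array(0, dim(a)), a), a + 0)
  expect_identical(combineSideWindows(a, a), 2 * a)
  expect_identical(combineSideWindows(a, b), a + b)
})

test_that("clamped corrections never exceed the uncorrected counts", {
  set.seed(45)
  p2 <- array(rpois(125, 40), c(5, 5, 5))
  p1 <- array(rpois(125, 15), c(5, 5, 5))
  p3 <- array(rpois(125, 15), c(5, 5, 5))
  p4 <- array(rpois(125, 25), c(5, 5, 5))
  expect_true(all(dewCorrect(p2, p4) <= p2))
  expect_true(all(tewCorrect(p2, p1, p3) <= p2))
  expect_true(all(dewCorrect(p2, p4) >= 0))
})

test_that("DEW with k = 1 removes the downscatter-window total on expectation images", {
  set.seed(46)
  e2 <- array(runif(4 * 4 * 6, 10, 60), c(4, 4, 6))
  e4 <- array(runif(4 * 4 * 6, 0, 9), c(4, 4, 6))
  out <- dewCorrect(e2, e4, dewParams(1), clamp = FALSE)
  expect_equal(sum(e2) - sum(out), sum(e4), tolerance = 1e-12)
})

test_that("TEW estimates the true injected main-window scatter better than DEW", {
  st <- smallStudy()
  pri <- forwardProject(st$phantom, st$geom, psf = psfModel(), mu = st$mu)
  acq <- synthesizeAcquisition(pri, seed = 11)
  tl <- componentTallies(acq)
  scatterCols <- c("high_energy_scatter", "xray_peak", "bremsstrahlung")
  trueScatter <- sum(tl["W2", scatterCols])
  tewEst <- sum(windowCounts(acq, "W1")) + sum(windowCounts(acq, "W3"))
  dewEst <- 1 * sum(windowCounts(acq, "W4"))
  expect_lt(abs(tewEst - trueScatter), abs(dewEst - trueScatter))
})

test_that("ProjectionSet-level correction tracks provenance and window needs", {
  st <- smallStudy(n = 16L, voxel = 16, nProj = 8L)
  pri <- forwardProject(st$phantom, st$geom)
  acq <- synthesizeAcquisition(pri, seed = 2)
  cor <- correctProjections(acq, "tew")
  expect_identical(windowLabels(cor), "W2")
  steps <- vapply(provenance(cor), `[[`, "", "step")
  expect_true("scatter_correction" %in% steps)
  expect_identical(provenance(cor)[[length(steps)]]$method, "tew")
  none <- correctProjections(acq, "none")
  expect_identical(windowCounts(none, "W2"), windowCounts(acq, "W2"))
  dew0 <- correctProjections(acq, "dew", params = dewParams(0))
  expect_identical(windowCounts(dew0, "W2") * 1, windowCounts(acq, "W2") * 1)
  onlyW2 <- correctProjections(acq, "none")
  expect_error(correctProjections(onlyW2, "tew"), "lacks window")
})
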