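test_that("VOIs: zero erosion keeps the full labelled sphere, background cylinder respects radius", {
  st <- smallStudy()
  vois <- makeVois(st$phantom, erosionMargin = 0L)
  lab <- regionLabels(st$phantom)
  for (i in seq_along(vois@sphereMasks)) {
    m <- vois@sphereMasks[[i]]
    expect_identical(m, lab == (1L + i))
  }
  cc <- hospect:::axisCoords(st$phantom@grid)
  r2 <- outer(cc[[1]]^2, cc[[2]]^2, "+")
  idx <- which(vois@backgroundMask, arr.ind = TRUE)
  expect_true(all(r2[idx[, 1:2]] <= 25^2))
  expect_true(all(lab[vois@backgroundMask] == 1L))
  expect_identical(unname(vois@trueConc["background"]), 312 / 6200)
})

test_that("erosion shrinks a sphere VOI by at most one voxel shell and can empty it", {
  sp <- sphereSpec(c(18, 0, 0), 31.3, 2, 1)
  ph <- buildJaszczak(gridSpec(c(96L, 96L, 80L), 1), sp,
                      backgroundConc = 0.05, innerDiameter = 80,
                      innerHeight = 60, wallThickness = 7)
  vois <- makeVois(ph, erosionMargin = 1L, bgRadius = 25, bgHeight = 30)
  vEroded <- sum(vois@sphereMasks[[1]]) * voxelVolume(ph)
  vAnalytic <- pi / 6 * 31.3^3 / 1000
  expect_lt(vEroded, vAnalytic)
  # removed voxels do not exceed a one-voxel surface shell (4 pi r^2 dr)
  shell <- 4 * pi * (31.3 / 2)^2 * 1.5 / 1000
  expect_lt(vAnalytic - vEroded, shell)
  # a sphere thinner than the margin erodes away, with its name in the error
  st <- smallStudy()   # 8 mm voxels: smallest spheres are 1-2 voxels
  expect_error(makeVois(st$phantom, erosionMargin = 2L), "sphere_")
})

test_that("CRC is 1 on the truth and invariant to global scaling", {
  st <- smallStudy()
  vois <- makeVois(st$phantom, erosionMargin = 0L)
  truth <- activityMap(st$phantom)
  expect_equal(unname(crc(truth, vois)), rep(1, 6), tolerance = 1e-12)
  expect_equal(crc(3.7 * truth, vois), crc(truth, vois), tolerance = 1e-12)
})

test_that("CRC and CNR match hand arithmetic on a toy volume", {
  vois <- toyVois()
  vol <- array(c(40, 60, 4, 6), c(4, 1, 1))
  # CRC: (mean(40,60)/10) / (mean(4,6)/1) = 5 / 5 = 1
  expect_equal(unname(crc(vol, vois)), 1)
  vol2 <- array(c(40, 80, 4, 6), c(4, 1, 1))
  expect_equal(unname(crc(vol2, vois)), (60 / 10) / (5 / 1))
  # CNR: |60 - 5| / sd(c(4,6)) = 55 / sqrt(2)
  expect_equal(unname(cnr(vol2, vois)), 55 / sqrt(2), tolerance = 1e-12)
  # equal means give CNR 0; positive scaling leaves CNR unchanged
  vol3 <- array(c(5, 5, 4, 6), c(4, 1, 1))
  expect_equal(unname(cnr(vol3, vois)), 0)
  expect_equal(cnr(2.5 * vol2, vois), cnr(vol2, vois), tolerance = 1e-12)
  # degenerate backgrounds are errors
  expect_error(cnr(array(c(1, 2, 3, 3), c(4, 1, 1)), vois), "zero background")
  expect_error(crc(array(c(1, 2, 0, 0), c(4, 1, 1)), vois), "background")
})

test_that("sigmoid fit recovers noise-free parameters and obeys its asymptote", {
  x <- c(9.9, 12.4, 15.4, 19.8, 24.8, 31.3) / 4.5
  y <- 1 / (1 + exp(-2 * (x - 3))) - 0.1
  fit <- fitSigmoid(x, y)
  expect_identical(fit@a, 1)
  expect_equal(fit@b, 2, tolerance = 1e-6)
  expect_equal(fit@c, 3, tolerance = 1e-6)
  expect_equal(fit@d, 0.1, tolerance = 1e-6)
  expect_lt(fit@residualSS, 1e-12)
  # S(x) -> 1 - d as x grows
  expect_equal(hospect:::sigmoidFun(1e6, fit@b, fit@c, fit@d), 1 - fit@d,
               tolerance = 1e-9)
  expect_error(fitSigmoid(x[1:2], y[1:2]), "3 points")
})

test_that("sigmoid fit is robust to measurement noise across seeds", {
  x <- c(9.9, 12.4, 15.4, 19.8, 24.8, 31.3) / 4.5
  y <- 1 / (1 + exp(-2 * (x - 3))) - 0.1
  set.seed(99)
  pars <- replicate(500, {
    fit <- fitSigmoid(x, y + rnorm(length(x), 0, 0.02))
    c(fit@b, fit@c, fit@d)
  })
  med <- apply(pars, 1, median)
  expect_true(all(abs(med - c(2, 3, 0.1)) / c(2, 3, 0.1) < 0.10))
})

test_that("FWHM measurement matches the analytic Gaussian width", {
  xg <- seq_len(61)
  prof <- exp(-(xg - 31)^2 / (2 * 5^2))
  expect_equal(measureFwhm(prof, pixelSize = 1), 2.3548 * 5,
               tolerance = 0.01)
  expect_equal(measureFwhm(100 * prof, 1), measureFwhm(prof, 1),
               tolerance = 1e-12)
  set.seed(17)
  fws <- replicate(100, measureFwhm(prof + rnorm(61, 0, 0.01), 1))
  expect_equal(mean(fws), 2.3548 * 5, tolerance = 0.03)
  expect_error(measureFwhm(seq(0, 1, length.out = 20)), "boundary")
})
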