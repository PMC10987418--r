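test_that("forward projection conserves counts and scales with activity and time", {
  st <- smallStudy()
  pri <- forwardProject(st$phantom, st$geom)   # no PSF, no attenuation
  p <- windowCounts(pri, "W2")
  totalMBq <- sum(activityMap(st$phantom)) * voxelVolume(st$phantom)
  expected <- totalMBq * 100 * st$geom@timePerProjection
  tots <- apply(p, 3, sum)
  expect_lt((max(tots) - min(tots)) / mean(tots), 1e-6)
  expect_equal(mean(tots), expected, tolerance = 1e-9)
  # linear in time per projection
  g2 <- acquisitionGeometry(nProjections = st$geom@nProjections,
                            timePerProjection = 60,
                            detectorMatrix = st$geom@detectorMatrix,
                            pixelSize = st$geom@pixelSize)
  p2 <- windowCounts(forwardProject(st$phantom, st$geom, sensitivity = 100), "W2")
  p3 <- windowCounts(forwardProject(st$phantom, g2, sensitivity = 100), "W2")
  expect_equal(sum(p3), 2 * sum(p2), tolerance = 1e-12)
})

test_that("zero activity projects to zero", {
  grid <- gridSpec(c(16L, 16L, 16L), 16)
  geom <- acquisitionGeometry(nProjections = 4L, detectorMatrix = c(16L, 16L),
                              pixelSize = 16)
  ph <- buildJaszczak(grid, spheres = NULL, backgroundConc = 0)
  expect_true(all(windowCounts(forwardProject(ph, geom), "W2") == 0))
})

test_that("a hot voxel projects to a Gaussian spot with the PSF's FWHM", {
  grid <- gridSpec(c(64L, 64L, 64L), 4)
  geom <- acquisitionGeometry(nProjections = 1L, detectorMatrix = c(64L, 64L),
                              pixelSize = 4)
  psf <- psfModel()
  x <- array(0, c(64, 64, 64)); x[33, 33, 33] <- 100
  P <- hospect:::makeProjector(grid, geom, psf = psf)
  pr <- hospect:::projForward(P, x)
  fw <- measureFwhm(pr[, 33, 1], pixelSize = 4)
  # voxel 33 sits 2 mm from the axis: 29.8 cm from the collimator
  expect_equal(fw, fwhmAt(psf, 29.8), tolerance = 0.05)
})

test_that("the linear FWHM model evaluates and inverts", {
  psf <- psfModel(4, 0.55)
  expect_equal(fwhmAt(psf, 0), 4)
  d <- seq(0, 40, by = 5)
  expect_true(all(diff(fwhmAt(psf, d)) >= 0))
  # recover the model from two sampled points
  f1 <- fwhmAt(psf, 10); f2 <- fwhmAt(psf, 30)
  slope <- (f2 - f1) / 20
  expect_equal(slope, 0.55, tolerance = 1e-12)
  expect_equal(f1 - slope * 10, 4, tolerance = 1e-12)
  expect_error(fwhmAt(psf, -1), "distance")
})

test_that("scatter-free spectrum model yields empty side windows and Poisson main window", {
  st <- smallStudy(n = 16L, voxel = 16, nProj = 8L)
  pri <- forwardProject(st$phantom, st$geom)
  f <- matrix(0, 4, 4, dimnames = list(c("W1", "W2", "W3", "W4"),
                                       hospect:::COMPONENT_NAMES))
  f[, "photopeak_80keV_and_scatter"] <- 1
  m <- spectrumComponentModel(f, rateScale = c(W1 = 0, W2 = 1, W3 = 0, W4 = 0))
  kern <- scatterKernels(photopeakUnscattered = 1)
  acq <- synthesizeAcquisition(pri, m, kern, seed = 9, decay = NULL)
  expect_true(all(windowCounts(acq, "W1") == 0))
  expect_true(all(windowCounts(acq, "W3") == 0))
  expect_true(all(windowCounts(acq, "W4") == 0))
  ref <- realizeCounts(pri, seed = 9, decay = NULL)
  expect_identical(windowCounts(acq, "W2"), windowCounts(ref, "W2") * 1)
})

test_that("synthesis is reproducible, tallies are exact, and totals follow the rate scales", {
  st <- smallStudy()
  pri <- forwardProject(st$phantom, st$geom, psf = psfModel(), mu = st$mu)
  a1 <- synthesizeAcquisition(pri, seed = 21)
  a2 <- synthesizeAcquisition(pri, seed = 21)
  expect_identical(windowCounts(a1), windowCounts(a2))
  tl <- componentTallies(a1)
  expect_identical(sum(tl), sum(vapply(windowCounts(a1), sum, 0)))
  # realized per-window totals track rateScale x W2 primary total (3 sigma)
  m <- spectrumComponentModel()
  T2 <- sum(windowCounts(pri, "W2"))
  meanDecay <- mean(decayActivity(1, st$geom@startTime +
    (seq_len(st$geom@nProjections) - 1) * st$geom@timePerProjection / 3600))
  for (w in c("W1", "W2", "W3", "W4")) {
    expTot <- m@rateScale[[w]] * T2 * meanDecay
    expect_lt(abs(sum(windowCounts(a1, w)) - expTot), 4 * sqrt(expTot))
  }
  # per-window component proportions match the model within 3 sigma
  for (w in c("W2", "W4")) {
    n <- sum(tl[w, ])
    p <- m@fractions[w, "high_energy_scatter"]
    expect_lt(abs(tl[w, "high_energy_scatter"] / n - p),
              3 * sqrt(p * (1 - p) / n))
  }
})

test_that("flat-field realizations are Poisson: variance tracks the mean", {
  grid <- gridSpec(c(64L, 64L, 64L), 4)
  geom <- acquisitionGeometry(nProjections = 4L, detectorMatrix = c(64L, 64L),
                              pixelSize = 4)
  flat <- array(200, c(64, 64, 4))
  ps <- new("ProjectionSet", counts = list(W2 = flat), geometry = geom,
            windows = defaultWindows()[2, ], tallies = matrix(numeric(0), 0, 0),
            provenance = list())
  r <- realizeCounts(ps, seed = 31, decay = NULL)
  v <- as.numeric(windowCounts(r, "W2"))
  expect_equal(var(v) / mean(v), 1, tolerance = 0.05)
})

test_that("decay across the acquisition dims later projections", {
  st <- smallStudy(n = 16L, voxel = 16, nProj = 8L)
  geomLate <- acquisitionGeometry(nProjections = 8L,
                                  detectorMatrix = c(16L, 16L),
                                  pixelSize = 16, timePerProjection = 3600)
  pri <- forwardProject(st$phantom, geomLate)
  r <- realizeCounts(pri, seed = 5)   # 1 h per projection: visible decay
  tots <- apply(windowCounts(r, "W2"), 3, sum)
  expected <- sum(windowCounts(pri, "W2")[, , 1]) *
    decayActivity(1, 0:7, decayParams())
  expect_equal(tots / expected, rep(1, 8), tolerance = 0.02)
  # kernels wider than the detector are a configuration error
  kern <- scatterKernels(scales = c(photopeak_80keV_and_scatter = 2,
                                    high_energy_scatter = 100,
                                    xray_peak = 6, bremsstrahlung = 8))
  expect_error(synthesizeAcquisition(pri, kernels = kern),
               "wider than the detector")
})
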