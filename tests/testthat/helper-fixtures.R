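# Shared small fixtures, built in code.

# a small Jaszczak-style phantom and matched geometry for fast end-to-end runs
smallStudy <- function(n = 31L, voxel = 8, nProj = 16L) {
  grid <- gridSpec(c(n, n, n), voxel)
  geom <- acquisitionGeometry(nProjections = nProj,
                              detectorMatrix = c(n, n), pixelSize = voxel)
  phantom <- buildJaszczak(grid, jaszczakSpheres())
  list(grid = grid, geom = geom, phantom = phantom,
       mu = attenuationMap(phantom))
}

# uniform-intensity disk volume plus masks, for reconstruction tests
diskVolume <- function(n = 32L, voxel = 8, value = 5, radiusMm = NULL,
                       slices = NULL) {
  grid <- gridSpec(c(n, n, n), voxel)
  cc <- hospect:::axisCoords(grid)
  r2 <- outer(cc[[1]]^2, cc[[2]]^2, "+")
  if (is.null(radiusMm)) radiusMm <- n * voxel * 0.3
  if (is.null(slices)) slices <- seq(n %/% 2 - 2L, n %/% 2 + 2L)
  x <- array(0, c(n, n, n))
  inner <- array(FALSE, c(n, n, n))
  for (k in slices) x[, , k][r2 <= radiusMm^2] <- value
  for (k in slices[-c(1, length(slices))])
    inner[, , k][r2 <= (radiusMm * 0.85)^2] <- TRUE
  list(grid = grid, volume = x, innerMask = inner, value = value)
}

# hand-built VoiSet on a tiny grid: 2 sphere voxels + 2 background voxels
toyVois <- function(dims = c(4L, 1L, 1L)) {
  s <- array(FALSE, dims); s[1:2, 1, 1] <- TRUE
  b <- array(FALSE, dims); b[3:4, 1, 1] <- TRUE
  new("VoiSet", sphereMasks = list(toy = s), backgroundMask = b,
      trueConc = c(toy = 10, background = 1))
}
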