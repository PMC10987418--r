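## Rotation-based parallel-beam projector with a matched (exact transpose)
## adjoint. The in-plane rotation is a sparse linear operator; the forward
## rotation uses the splatting (transpose-interpolation) form so that voxel
## mass is conserved exactly, and the backprojector applies the literal
## matrix transpose, giving <Ax, y> == <x, A'y> to machine precision.
## Attenuation enters as a fixed diagonal factor computed from the rotated
## mu map; the optional distance-dependent PSF is a per-depth-plane
## separable Gaussian convolution (symmetric, hence self-adjoint).

## Bilinear interpolation matrix for an in-plane rotation by `phi` radians
## about the world origin: rows are output pixels, row sums are 1 in the
## interior, weights falling outside the grid are dropped.
makeInterpMat <- function(grid, phi) {
  nx <- grid@shape[1]; ny <- grid@shape[2]
  cc <- axisCoords(grid)
  X <- rep(cc[[1]], times = ny)
  Y <- rep(cc[[2]], each = nx)
  cphi <- cos(phi); sphi <- sin(phi)
  xi <- cphi * X + sphi * Y    # inverse-rotated sample point
  yi <- -sphi * X + cphi * Y
  fi <- (xi - grid@origin[1]) / grid@voxelSize[1] + 1
  fj <- (yi - grid@origin[2]) / grid@voxelSize[2] + 1
  i0 <- floor(fi); j0 <- floor(fj)
  fx <- fi - i0; fy <- fj - j0
  o <- seq_len(nx * ny)
  rows <- integer(0); cols <- integer(0); w <- numeric(0)
  for (corner in 1:4) {
    ii <- i0 + (corner == 2L | corner == 4L)
    jj <- j0 + (corner >= 3L)
    wt <- (if (corner %% 2L == 1L) 1 - fx else fx) *
          (if (corner <= 2L) 1 - fy else fy)
    ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny & wt > 0
    rows <- c(rows, o[ok])
    cols <- c(cols, ii[ok] + (jj[ok] - 1L) * nx)
    w <- c(w, wt[ok])
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = w, dims = c(nx * ny, nx * ny))
}

## truncated, normalized Gaussian convolution matrix (symmetric Toeplitz)
gaussConvMat <- function(n, fwhmPx) {
  if (fwhmPx <= 1e-9) return(diag(n))
  sigma <- fwhmPx / (2 * sqrt(2 * log(2)))
  K <- min(n - 1L, ceiling(4 * sigma))
  k <- exp(-(0:K)^2 / (2 * sigma^2))
  k <- k / (k[1] + 2 * sum(k[-1]))
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  B <- matrix(0, n, n)
  B[D <= K] <- k[D[D <= K] + 1L]
  B
}

#' System-resolution model: FWHM at a distance
#'
#' Evaluates the linear resolution model FWHM(d) = intrinsic + slope * d.
#'
#' @param psf a [PsfModel-class].
#' @param distance cm from the collimator face (>= 0, vectorised).
#' @return FWHM in mm.
#' @export
fwhmAt <- function(psf, distance) {
  stopifnot(is(psf, "PsfModel"))
  if (any(distance < 0)) stop("'distance' must be >= 0", call. = FALSE)
  psf@fwhmIntrinsic + psf@fwhmSlope * distance
}

## Build the projector model: per-angle rotation operators, attenuation
## factors and per-depth blur matrices. Detector u maps to grid x, detector
## v to grid z; the detector sits on the +y side of the rotated frame.
makeProjector <- function(grid, geom, psf = NULL, mu = NULL) {
  stopifnot(is(grid, "GridSpec"), is(geom, "AcquisitionGeometry"))
  nx <- grid@shape[1]; ny <- grid@shape[2]; nz <- grid@shape[3]
  if (nx != ny || abs(grid@voxelSize[1] - grid@voxelSize[2]) > 1e-9)
    stop("projector requires square in-plane voxels (nx == ny)", call. = FALSE)
  if (!identical(geom@detectorMatrix, as.integer(c(nx, nz))) ||
      abs(geom@pixelSize - grid@voxelSize[1]) > 1e-9)
    stop("detector matrix/pixel size does not match the volume grid",
         call. = FALSE)
  if (!is.null(mu) && !identical(dim(mu), as.integer(grid@shape)))
    stop("'mu' grid does not match the volume grid", call. = FALSE)
  nA <- geom@nProjections
  angles <- (seq_len(nA) - 1) * geom@angleSpan / nA * pi / 180
  S <- lapply(angles, function(th) Matrix::t(makeInterpMat(grid, th)))
  att <- NULL
  if (!is.null(mu)) {
    dyCm <- grid@voxelSize[2] / 10
    Mmu <- mu; dim(Mmu) <- c(nx * ny, nz)
    att <- lapply(S, function(Sa) {
      mr <- as.matrix(Sa %*% Mmu)
      dim(mr) <- c(nx, ny, nz)
      f <- array(0, c(nx, ny, nz))
      acc <- matrix(0, nx, nz)      # attenuation accumulated toward detector
      for (j in ny:1) {
        f[, j, ] <- exp(-dyCm * (acc + 0.5 * mr[, j, ]))
        acc <- acc + mr[, j, ]
      }
      f
    })
  }
  Bu <- Bv <- NULL
  if (!is.null(psf)) {
    cy <- axisCoords(grid)[[2]]
    dCm <- pmax(0, (geom@orbitRadius - cy)) / 10
    fw <- fwhmAt(psf, dCm) / grid@voxelSize[1]
    Bu <- lapply(fw, function(f) gaussConvMat(nx, f))
    Bv <- lapply(fw, function(f) gaussConvMat(nz, f))
  }
  list(grid = grid, geom = geom, S = S, att = att, Bu = Bu, Bv = Bv,
       shape = c(nx, ny, nz))
}

## forward projection: x (nx,ny,nz) -> sinogram (nx, nz, length(angles))
projForward <- function(P, x, angles = seq_along(P$S)) {
  nx <- P$shape[1]; ny <- P$shape[2]; nz <- P$shape[3]
  X <- x; dim(X) <- c(nx * ny, nz)
  out <- array(0, c(nx, nz, length(angles)))
  for (ia in seq_along(angles)) {
    a <- angles[ia]
    V <- as.matrix(P$S[[a]] %*% X)
    dim(V) <- c(nx, ny, nz)
    if (!is.null(P$att)) V <- V * P$att[[a]]
    if (!is.null(P$Bu))
      for (j in seq_len(ny)) V[, j, ] <- P$Bu[[j]] %*% V[, j, ] %*% P$Bv[[j]]
    out[, , ia] <- colSums(aperm(V, c(2, 1, 3)))
  }
  out
}

## matched adjoint of projForward
projBack <- function(P, y, angles = seq_along(P$S)) {
  nx <- P$shape[1]; ny <- P$shape[2]; nz <- P$shape[3]
  X <- matrix(0, nx * ny, nz)
  for (ia in seq_along(angles)) {
    a <- angles[ia]
    V <- aperm(array(y[, , ia], c(nx, nz, ny)), c(1, 3, 2))
    if (!is.null(P$Bu))
      for (j in seq_len(ny)) V[, j, ] <- P$Bu[[j]] %*% V[, j, ] %*% P$Bv[[j]]
    if (!is.null(P$att)) V <- V * P$att[[a]]
    dim(V) <- c(nx * ny, nz)
    X <- X + as.matrix(Matrix::crossprod(P$S[[a]], V))
  }
  dim(X) <- c(nx, ny, nz)
  X
}
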