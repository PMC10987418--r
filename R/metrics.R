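## Image-quality scoring: VOI construction, CRC / CNR, sigmoid CRC-curve
## fitting, and FWHM measurement on 1D profiles.

## one step of 6-connected binary erosion, iterated n times
erode3d <- function(mask, n = 1L) {
  d <- dim(mask)
  for (it in seq_len(n)) {
    m <- mask
    sh <- function(ax, by) {
      out <- array(FALSE, d)
      idx <- lapply(d, seq_len)
      src <- idx; dst <- idx
      if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
      else { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
      out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
      out
    }
    mask <- m & sh(1, 1) & sh(1, -1) & sh(2, 1) & sh(2, -1) &
      sh(3, 1) & sh(3, -1)
  }
  mask
}

#' Build volumes of interest for CRC / CNR scoring
#'
#' Sphere VOIs are the labelled sphere voxels eroded by `erosionMargin`
#' voxels (avoiding border voxels affected by partial volume). The
#' background VOI is a cylinder of radius `bgRadius` about the phantom axis,
#' centred on the transverse plane through the sphere centres and restricted
#' to the background compartment.
#'
#' @param phantom a labelled [VoxelPhantom-class].
#' @param erosionMargin voxels of 6-connected erosion applied to each sphere
#'   VOI (default 1).
#' @param bgRadius mm, background cylinder radius (default 25 mm).
#' @param bgHeight mm, background cylinder height (default 40 mm).
#' @return A [VoiSet-class].
#' @export
makeVois <- function(phantom, erosionMargin = 1L, bgRadius = 25,
                     bgHeight = 40) {
  stopifnot(is(phantom, "VoxelPhantom"))
  lab <- phantom@labels
  reg <- phantom@regions
  sphereRows <- reg[reg$label >= 2L & reg$label <= 7L, , drop = FALSE]
  if (nrow(sphereRows) == 0L) stop("phantom has no sphere labels", call. = FALSE)
  masks <- list()
  for (i in seq_len(nrow(sphereRows))) {
    m <- lab == sphereRows$label[i]
    if (erosionMargin > 0) m <- erode3d(m, erosionMargin)
    if (!any(m))
      stop(sprintf("erosion empties the VOI of %s", sphereRows$region[i]),
           call. = FALSE)
    masks[[sphereRows$region[i]]] <- m
  }
  cc <- axisCoords(phantom@grid)
  ## sphere-centre plane: mean axial coordinate of the sphere voxels
  kIdx <- arrayInd(which(lab >= 2L & lab <= 7L), dim(lab))[, 3]
  z0 <- mean(cc[[3]][kIdx])
  r2 <- outer(cc[[1]]^2, cc[[2]]^2, "+")
  in2d <- r2 <= bgRadius^2
  bg <- array(FALSE, dim(lab))
  for (k in which(abs(cc[[3]] - z0) <= bgHeight / 2)) bg[, , k] <- in2d
  bg <- bg & lab == 1L
  conc <- setNames(c(sphereRows$conc_MBq_ml,
                     reg$conc_MBq_ml[reg$label == 1L]),
                   c(sphereRows$region, "background"))
  new("VoiSet", sphereMasks = masks, backgroundMask = bg, trueConc = conc)
}

#' Contrast recovery coefficients
#'
#' For each sphere i, CRC_i = (measured / true concentration in the sphere)
#' divided by (measured / true concentration in the background). A volume
#' equal to the truth gives CRC = 1 for every sphere, and any global
#' intensity scale cancels.
#'
#' @param volume reconstructed 3D array (any global scale).
#' @param vois a [VoiSet-class].
#' @return named numeric, CRC per sphere.
#' @export
crc <- function(volume, vois) {
  stopifnot(is(vois, "VoiSet"))
  bgMeas <- mean(volume[vois@backgroundMask])
  if (!is.finite(bgMeas) || bgMeas <= 0)
    stop("background measurement is zero or undefined; CRC undefined",
         call. = FALSE)
  bgRel <- bgMeas / vois@trueConc[["background"]]
  vapply(names(vois@sphereMasks), function(s) {
    (mean(volume[vois@sphereMasks[[s]]]) / vois@trueConc[[s]]) / bgRel
  }, 0)
}

#' Contrast-to-noise ratios
#'
#' For each sphere j, CNR_j = |mean(sphere_j) - mean(background)| /
#' sd(background), the standard deviation being the sample (n-1) standard
#' deviation over background voxels.
#'
#' @param volume reconstructed 3D array.
#' @param vois a [VoiSet-class]; the background VOI needs >= 2 voxels.
#' @return named numeric, CNR per sphere.
#' @export
cnr <- function(volume, vois) {
  stopifnot(is(vois, "VoiSet"))
  bgVox <- volume[vois@backgroundMask]
  if (length(bgVox) < 2L) stop("background VOI needs >= 2 voxels", call. = FALSE)
  s <- sd(bgVox)
  if (s == 0) stop("zero background standard deviation; CNR undefined",
                   call. = FALSE)
  m <- mean(bgVox)
  vapply(names(vois@sphereMasks), function(sp) {
    abs(mean(volume[vois@sphereMasks[[sp]]]) - m) / s
  }, 0)
}

sigmoidFun <- function(x, b, cc, d) 1 / (1 + exp(-b * (x - cc))) - d

#' Fit a sigmoid to a CRC curve
#'
#' Least-squares fit of S(x) = a / (1 + exp(-b (x - c))) - d with the
#' plateau fixed at a = 1 (contrast recovery tends to 1 for large spheres).
#' x is sphere diameter / FWHM. Bounds: b > 0, c > 0, d in \[0, 1\].
#'
#' @param x numeric, sphere diameter / FWHM per point (>= 3 points).
#' @param y numeric, CRC per point.
#' @param init named start values c(b=, c=, d=).
#' @param maxIter maximum optimizer iterations.
#' @return A [SigmoidFit-class].
#' @export
fitSigmoid <- function(x, y, init = c(b = 1, c = 2, d = 0), maxIter = 500) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(x <= 0)) stop("x values must be > 0", call. = FALSE)
  lower <- c(1e-8, 1e-8, 0)
  upper <- c(Inf, Inf, 1)
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + exp(-b * (x - cc))) - d, data = df,
                      start = list(b = init[["b"]], cc = init[["c"]],
                                   d = init[["d"]]),
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = maxIter)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    b <- cf[["b"]]; cc <- cf[["cc"]]; d <- cf[["d"]]
  } else {
    rss <- function(p) sum((y - sigmoidFun(x, p[1], p[2], p[3]))^2)
    op <- stats::optim(pmin(pmax(init, lower), c(10, 10, 1)), rss,
                       method = "L-BFGS-B", lower = lower, upper = upper,
                       control = list(maxit = maxIter))
    if (op$convergence != 0)
      stop(sprintf(
        "sigmoid fit did not converge; best iterate b=%.4g c=%.4g d=%.4g",
        op$par[1], op$par[2], op$par[3]), call. = FALSE)
    b <- op$par[1]; cc <- op$par[2]; d <- op$par[3]
  }
  pred <- sigmoidFun(x, b, cc, d)
  new("SigmoidFit", a = 1, b = unname(b), c = unname(cc), d = unname(d),
      residualSS = sum((y - pred)^2), fitted = pred)
}

#' Measure FWHM of a 1D peaked profile
#'
#' Background-subtracts the profile (minimum value), finds the dominant
#' peak, and locates the two half-maximum crossings by linear interpolation.
#'
#' @param profile numeric vector with a single dominant peak.
#' @param pixelSize mm per sample.
#' @return FWHM in mm.
#' @export
measureFwhm <- function(profile, pixelSize = 1) {
  p <- profile - min(profile)
  m <- which.max(p)
  half <- p[m] / 2
  if (m == 1L || m == length(p))
    stop("peak at profile boundary; no crossings", call. = FALSE)
  idxL <- which(p[1:(m - 1)] <= half)
  if (length(idxL) == 0L) stop("no left half-maximum crossing", call. = FALSE)
  iL <- max(idxL)
  xL <- iL + (half - p[iL]) / (p[iL + 1] - p[iL])
  iRrel <- which(p[(m + 1):length(p)] <= half)
  if (length(iRrel) == 0L) stop("no right half-maximum crossing", call. = FALSE)
  iR <- m + min(iRrel)
  xR <- iR - (half - p[iR]) / (p[iR - 1] - p[iR])
  (xR - xL) * pixelSize
}
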