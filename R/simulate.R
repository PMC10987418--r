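## Multi-window SPECT acquisition simulator: noiseless primary projections
## via the attenuated blurred projector, then per-window spectral components
## with Poisson counting noise and radioactive decay.

DEFAULT_SENSITIVITY <- 100  # detected counts per second per MBq in W2

#' Forward-project a phantom into noiseless primary projections
#'
#' Computes the expected photopeak (W2) primary counts for every projection
#' angle: an attenuated line-integral projector with an optional
#' distance-dependent Gaussian blur. Expected counts per voxel contribution
#' are concentration x voxel volume x sensitivity x time per projection.
#' Radioactive decay is not applied here (the projections refer to the
#' reference activity); [synthesizeAcquisition()] applies decay per
#' projection.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param geom an [AcquisitionGeometry-class]; detector matrix and pixel size
#'   must match the phantom grid (u = x, v = z axes).
#' @param psf a [PsfModel-class], or NULL for an ideal (unblurred) system.
#' @param mu 3D attenuation array (1/cm) on the phantom grid, or NULL for no
#'   attenuation.
#' @param sensitivity detected counts per second per MBq.
#' @return A single-window [ProjectionSet-class] ("W2") of expected counts.
#' @export
forwardProject <- function(phantom, geom, psf = NULL, mu = NULL,
                           sensitivity = DEFAULT_SENSITIVITY) {
  stopifnot(is(phantom, "VoxelPhantom"))
  P <- makeProjector(phantom@grid, geom, psf = psf, mu = mu)
  xMBq <- phantom@activity * voxelVolume(phantom)
  proj <- projForward(P, xMBq) * sensitivity * geom@timePerProjection
  wt <- defaultWindows()
  new("ProjectionSet", counts = list(W2 = proj), geometry = geom,
      windows = wt[wt$label == "W2", , drop = FALSE],
      tallies = matrix(numeric(0), 0, 0),
      provenance = list(list(step = "forward_project",
                             sensitivity = sensitivity,
                             psf = !is.null(psf), attenuated = !is.null(mu))))
}

#' Spatial kernels of the spectrum components
#'
#' Configures how each spectrum component is distributed spatially relative
#' to the primary projection. The photopeak component keeps a fraction of
#' its counts unscattered (identity kernel) and spreads the rest with a
#' medium Gaussian; the high-energy downscatter -- photons that pass through
#' the collimator septa almost unhindered -- is spread with a very broad
#' Gaussian, as are the X-ray and bremsstrahlung contributions. Kernel
#' FWHMs are multiples of the system FWHM at the orbit radius.
#'
#' @param psf a [PsfModel-class] used to set the base FWHM.
#' @param orbitRadius mm; base FWHM is evaluated at this distance.
#' @param photopeakUnscattered fraction of the photopeak component left
#'   unblurred.
#' @param scales named FWHM multipliers for the blurred parts of the four
#'   components.
#' @return list of per-component kernel settings (identity fraction and
#'   blur FWHM in mm).
#' @export
scatterKernels <- function(psf = psfModel(), orbitRadius = 300,
                           photopeakUnscattered = 0.6,
                           scales = c(photopeak_80keV_and_scatter = 2,
                                      high_energy_scatter = 10,
                                      xray_peak = 6,
                                      bremsstrahlung = 8)) {
  stopifnot(photopeakUnscattered >= 0, photopeakUnscattered <= 1)
  base <- fwhmAt(psf, orbitRadius / 10)
  lapply(setNames(COMPONENT_NAMES, COMPONENT_NAMES), function(cn) {
    list(identityFraction = if (cn == "photopeak_80keV_and_scatter")
           photopeakUnscattered else 0,
         blurFwhm = base * scales[[cn]])
  })
}

## blur every projection of a stack with a fixed-FWHM separable Gaussian,
## renormalizing each projection to its original total (detector-edge
## truncation must not destroy counts: component totals are model inputs)
blurStack <- function(stack, fwhmMm, pixelSize) {
  if (fwhmMm <= 1e-9) return(stack)
  d <- dim(stack)
  Bu <- gaussConvMat(d[1], fwhmMm / pixelSize)
  Bv <- gaussConvMat(d[2], fwhmMm / pixelSize)
  out <- stack
  for (a in seq_len(d[3])) {
    pl <- Bu %*% stack[, , a] %*% Bv
    s0 <- sum(stack[, , a]); s1 <- sum(pl)
    if (s1 > 0) pl <- pl * (s0 / s1)
    out[, , a] <- pl
  }
  out
}

#' Synthesize a four-window acquisition with noise and decay
#'
#' Expands noiseless primary (W2 photopeak) projections into the four
#' acquisition windows: each window's expectation is a mixture of the
#' primary and blurred-primary component shapes, scaled so that per-window
#' component proportions match the spectrum model and per-window totals
#' follow the model's rate scales. Radioactive decay is applied per
#' projection (contiguous schedule starting at the geometry's `startTime`),
#' then independent Poisson noise is drawn per pixel and per component.
#' Realized per-window, per-component count totals are stored as tallies, so
#' tallies sum exactly to the total simulated counts.
#'
#' @param primary single-window [ProjectionSet-class] with the W2 expectation
#'   (see [forwardProject()]).
#' @param model a [SpectrumComponentModel-class].
#' @param kernels component kernel configuration from [scatterKernels()].
#' @param seed integer seed; draws are made window by window (W1..W4) and
#'   component by component in table order, pixels in array order.
#' @param decay a [DecayParams-class], or NULL to disable decay.
#' @return A [ProjectionSet-class] with windows W1..W4 and component tallies.
#' @export
synthesizeAcquisition <- function(primary, model = spectrumComponentModel(),
                                  kernels = scatterKernels(),
                                  seed = NULL, decay = decayParams()) {
  stopifnot(is(primary, "ProjectionSet"), is(model, "SpectrumComponentModel"))
  if (!"W2" %in% names(primary@counts))
    stop("'primary' must contain the W2 photopeak expectation", call. = FALSE)
  g <- primary@geometry
  Pw2 <- primary@counts[["W2"]]
  det_mm <- g@detectorMatrix * g@pixelSize
  for (k in kernels)
    if (k$blurFwhm > max(det_mm))
      stop("scatter kernel wider than the detector", call. = FALSE)

  nA <- g@nProjections
  tHours <- g@startTime + (seq_len(nA) - 1) * g@timePerProjection / 3600
  decayF <- if (is.null(decay)) rep(1, nA) else
    decayActivity(1, tHours, decay)

  ## primary and blurred-primary shapes, decay applied per projection
  shapes <- list(identity = sweep(Pw2, 3, decayF, "*"))
  blurred <- lapply(kernels, function(k)
    if (k$identityFraction < 1)
      sweep(blurStack(Pw2, k$blurFwhm, g@pixelSize), 3, decayF, "*")
    else NULL)

  wins <- rownames(model@fractions)
  tall <- matrix(0, length(wins), ncol(model@fractions),
                 dimnames = list(wins, colnames(model@fractions)))
  counts <- withSeed(seed, {
    out <- list()
    for (w in wins) {
      stack <- array(0, dim(Pw2))
      for (cn in colnames(model@fractions)) {
        share <- model@rateScale[[w]] * model@fractions[w, cn]
        if (share <= 0) next
        k <- kernels[[cn]]
        E <- if (k$identityFraction >= 1) share * shapes$identity else
          share * (k$identityFraction * shapes$identity +
                   (1 - k$identityFraction) * blurred[[cn]])
        cts <- array(rpois(length(E), E), dim(E))
        tall[w, cn] <- sum(cts)
        stack <- stack + cts
      }
      out[[w]] <- stack
    }
    out
  })
  new("ProjectionSet", counts = counts, geometry = g,
      windows = defaultWindows(), tallies = tall,
      provenance = c(primary@provenance,
                     list(list(step = "synthesize_acquisition",
                               seed = seed %||% NA_integer_,
                               rateScale = as.list(model@rateScale),
                               upstream = objectHash(Pw2)))))
}

#' Realize Poisson counts from expectation projections
#'
#' Draws independent Poisson counts around each pixel's expected value --
#' used to produce the scatter-free noisy reference acquisition from the
#' primary expectation (decay applied per projection as in
#' [synthesizeAcquisition()]).
#'
#' @param ps a [ProjectionSet-class] of expectations.
#' @param seed integer seed.
#' @param decay a [DecayParams-class], or NULL to disable decay.
#' @return A [ProjectionSet-class] of integer counts.
#' @export
realizeCounts <- function(ps, seed = NULL, decay = decayParams()) {
  stopifnot(is(ps, "ProjectionSet"))
  g <- ps@geometry
  nA <- g@nProjections
  tHours <- g@startTime + (seq_len(nA) - 1) * g@timePerProjection / 3600
  decayF <- if (is.null(decay)) rep(1, nA) else decayActivity(1, tHours, decay)
  counts <- withSeed(seed, lapply(ps@counts, function(E) {
    E <- sweep(E, 3, decayF, "*")
    array(rpois(length(E), E), dim(E))
  }))
  new("ProjectionSet", counts = counts, geometry = g, windows = ps@windows,
      tallies = ps@tallies,
      provenance = c(ps@provenance,
                     list(list(step = "realize_counts",
                               seed = seed %||% NA_integer_))))
}
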