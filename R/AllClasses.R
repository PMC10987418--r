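#' @import methods
#' @importFrom stats rmultinom rpois sd pt optim fft convolve quantile setNames
NULL

COMPONENT_NAMES <- c("photopeak_80keV_and_scatter", "high_energy_scatter",
                     "xray_peak", "bremsstrahlung")
WINDOW_LABELS <- c("W1", "W2", "W3", "W4")

#' GridSpec: a regular 3D voxel grid
#'
#' Describes the sampling grid of a voxel phantom or reconstructed volume:
#' number of voxels per axis, voxel size in mm, and the world-coordinate (mm)
#' of the centre of the first voxel.
#'
#' @slot shape integer(3), voxels per axis (x, y, z); all >= 1.
#' @slot voxelSize numeric(3), mm per voxel along each axis; all > 0.
#' @slot origin numeric(3), mm, world coordinate of the centre of voxel
#'   (1,1,1).
#' @exportClass GridSpec
setClass("GridSpec",
         representation(shape = "integer", voxelSize = "numeric",
                        origin = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (length(object@shape) != 3L || any(object@shape < 1L))
             msg <- c(msg, "'shape' must be 3 integers, all >= 1")
           if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
             msg <- c(msg, "'voxelSize' must be 3 positive numbers (mm)")
           if (length(object@origin) != 3L || any(!is.finite(object@origin)))
             msg <- c(msg, "'origin' must be 3 finite numbers (mm)")
           if (is.null(msg)) TRUE else msg
         })

#' @describeIn GridSpec-class Constructor. `voxelSize` may be a scalar
#'   (isotropic). Default origin centres the grid on the world origin.
#' @param shape integer(3) voxel counts.
#' @param voxelSize mm per voxel, scalar or length 3.
#' @param origin mm coordinate of the first voxel centre; default centres the
#'   grid at (0,0,0).
#' @return A [GridSpec-class] object.
#' @export
gridSpec <- function(shape = c(128L, 128L, 128L), voxelSize = 4,
                     origin = NULL) {
  shape <- as.integer(shape)
  voxelSize <- rep_len(as.numeric(voxelSize), 3L)
  if (is.null(origin))
    origin <- -(shape - 1L) / 2 * voxelSize
  new("GridSpec", shape = shape, voxelSize = voxelSize,
      origin = as.numeric(origin))
}

#' VoxelPhantom: activity, attenuation and region labels on a grid
#'
#' The digital phantom: an activity concentration map (MBq/ml), a linear
#' attenuation map (1/cm) and an integer region-label map sharing one
#' [GridSpec-class]. Labels: 0 = air, 1 = background, 2..7 = spheres
#' (smallest to largest), 8 = wall (cylinder and sphere shells).
#'
#' @slot grid a [GridSpec-class].
#' @slot activity 3D numeric array, MBq/ml, non-negative.
#' @slot mu 3D numeric array, 1/cm at the reference energy, non-negative.
#' @slot labels 3D integer array of region labels.
#' @slot regions data.frame with one row per region: `region`, `label`,
#'   `analyticVolume_ml` (geometric volume from the defining dimensions),
#'   `voxelVolume_ml` (volume of the voxelized region) and `conc_MBq_ml`.
#' @exportClass VoxelPhantom
setClass("VoxelPhantom",
         representation(grid = "GridSpec", activity = "array", mu = "array",
                        labels = "array", regions = "data.frame"),
         validity = function(object) {
           msg <- NULL
           sh <- object@grid@shape
           for (nm in c("activity", "mu", "labels")) {
             a <- slot(object, nm)
             if (!identical(dim(a), as.integer(sh)))
               msg <- c(msg, sprintf("'%s' dimensions do not match the grid", nm))
           }
           if (any(object@activity < 0)) msg <- c(msg, "negative activity")
           if (any(object@mu < 0)) msg <- c(msg, "negative attenuation")
           if (is.null(msg)) TRUE else msg
         })

#' AcquisitionGeometry: SPECT orbit and timing
#'
#' @slot nProjections integer, number of projection angles (>= 1).
#' @slot angleSpan degrees covered by the orbit, in (0, 360].
#' @slot timePerProjection seconds per projection (> 0).
#' @slot detectorMatrix integer(2), detector pixels (u, v).
#' @slot pixelSize mm, detector pixel pitch.
#' @slot orbitRadius mm, collimator face to rotation axis.
#' @slot startTime hours elapsed between the reference activity and the start
#'   of the acquisition (decay bookkeeping).
#' @exportClass AcquisitionGeometry
setClass("AcquisitionGeometry",
         representation(nProjections = "integer", angleSpan = "numeric",
                        timePerProjection = "numeric",
                        detectorMatrix = "integer", pixelSize = "numeric",
                        orbitRadius = "numeric", startTime = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (object@nProjections < 1L)
             msg <- c(msg, "'nProjections' must be >= 1")
           if (object@timePerProjection <= 0)
             msg <- c(msg, "'timePerProjection' must be > 0")
           if (object@angleSpan <= 0 || object@angleSpan > 360)
             msg <- c(msg, "'angleSpan' must be in (0, 360]")
           if (length(object@detectorMatrix) != 2L ||
               any(object@detectorMatrix < 1L))
             msg <- c(msg, "'detectorMatrix' must be 2 positive integers")
           if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
           if (object@orbitRadius <= 0) msg <- c(msg, "'orbitRadius' must be > 0")
           if (object@startTime < 0) msg <- c(msg, "'startTime' must be >= 0")
           if (is.null(msg)) TRUE else msg
         })

#' @describeIn AcquisitionGeometry-class Constructor with the study's
#'   clinical acquisition protocol as default: 120 projections of 30 s over
#'   360 degrees on a 128 x 128 matrix, orbit radius 300 mm.
#' @param nProjections,angleSpan,timePerProjection,detectorMatrix,pixelSize,orbitRadius,startTime
#'   see slots.
#' @return An [AcquisitionGeometry-class] object.
#' @export
acquisitionGeometry <- function(nProjections = 120L, angleSpan = 360,
                                timePerProjection = 30,
                                detectorMatrix = c(128L, 128L),
                                pixelSize = 4, orbitRadius = 300,
                                startTime = 0) {
  new("AcquisitionGeometry", nProjections = as.integer(nProjections),
      angleSpan = as.numeric(angleSpan),
      timePerProjection = as.numeric(timePerProjection),
      detectorMatrix = as.integer(detectorMatrix),
      pixelSize = as.numeric(pixelSize), orbitRadius = as.numeric(orbitRadius),
      startTime = as.numeric(startTime))
}

#' PsfModel: distance-dependent collimator-detector response
#'
#' A linear resolution model: the full width at half maximum of the system
#' point-spread function grows linearly with source-to-collimator distance,
#' FWHM(d) = fwhmIntrinsic + fwhmSlope * d. Typical of parallel-hole
#' collimators; defaults describe a medium-energy general-purpose collimator
#' imaging the 80.6 keV photopeak.
#'
#' @slot fwhmIntrinsic mm, FWHM at the collimator face (>= 0).
#' @slot fwhmSlope mm per cm of source-collimator distance (>= 0).
#' @exportClass PsfModel
setClass("PsfModel",
         representation(fwhmIntrinsic = "numeric", fwhmSlope = "numeric"),
         validity = function(object) {
           if (object@fwhmIntrinsic < 0 || object@fwhmSlope < 0)
             "PSF parameters must be non-negative" else TRUE
         })

#' @describeIn PsfModel-class Constructor.
#' @param fwhmIntrinsic mm at distance 0.
#' @param fwhmSlope mm/cm.
#' @return A [PsfModel-class] object.
#' @export
psfModel <- function(fwhmIntrinsic = 4, fwhmSlope = 0.55) {
  new("PsfModel", fwhmIntrinsic = as.numeric(fwhmIntrinsic),
      fwhmSlope = as.numeric(fwhmSlope))
}

#' SpectrumComponentModel: per-window spectral component fractions
#'
#' Parametric model of how counts in each acquisition energy window split
#' over the four Ho-166 spectrum components (80.6 keV photopeak and its
#' associated scatter, high-energy scattered gamma rays, characteristic X-ray
#' peak, bremsstrahlung X rays). Each row of `fractions` is one window and
#' sums to 1. `rateScale` gives each window's total count rate relative to
#' the main window W2.
#'
#' @slot fractions numeric matrix, rows = windows (W1..W4), columns = the four
#'   components; entries in \[0,1\], each row sums to 1 within 1e-9.
#' @slot rateScale named numeric, total-rate multiplier per window relative
#'   to W2 (so rateScale\["W2"\] = 1).
#' @exportClass SpectrumComponentModel
setClass("SpectrumComponentModel",
         representation(fractions = "matrix", rateScale = "numeric"),
         validity = function(object) {
           msg <- NULL
           f <- object@fractions
           if (!identical(colnames(f), COMPONENT_NAMES))
             msg <- c(msg, "fraction columns must be the four named components")
           if (any(f < 0 | f > 1)) msg <- c(msg, "fractions must lie in [0,1]")
           if (any(abs(rowSums(f) - 1) > 1e-9))
             msg <- c(msg, "each window's fractions must sum to 1 (within 1e-9)")
           if (!all(rownames(f) %in% names(object@rateScale)))
             msg <- c(msg, "every window needs a rateScale entry")
           if (any(object@rateScale < 0)) msg <- c(msg, "rateScale must be >= 0")
           if (is.null(msg)) TRUE else msg
         })

#' ProjectionSet: multi-window stacks of SPECT projections
#'
#' Per-energy-window stacks of 2D projections (detector u x v x angle) sharing
#' one acquisition geometry. `tallies`, when present, records the expected
#' per-window, per-component count totals injected by the simulator (ground
#' truth for scatter-estimation studies).
#'
#' @slot counts named list of 3D arrays (u, v, angle), one per window.
#' @slot geometry an [AcquisitionGeometry-class].
#' @slot windows data.frame describing the energy windows present (see
#'   [defaultWindows()]).
#' @slot tallies numeric matrix (windows x components) of simulated expected
#'   component totals, or a 0x0 matrix when unknown.
#' @slot provenance list of free-form provenance records (seed, corrections
#'   applied, upstream hashes).
#' @exportClass ProjectionSet
setClass("ProjectionSet",
         representation(counts = "list", geometry = "AcquisitionGeometry",
                        windows = "data.frame", tallies = "matrix",
                        provenance = "list"),
         validity = function(object) {
           msg <- NULL
           if (length(object@counts) == 0L)
             msg <- c(msg, "at least one window stack required")
           g <- object@geometry
           want <- c(g@detectorMatrix, g@nProjections)
           for (w in names(object@counts)) {
             a <- object@counts[[w]]
             if (!identical(dim(a), as.integer(want)))
               msg <- c(msg, sprintf("window '%s' stack is not %s", w,
                                     paste(want, collapse = "x")))
             if (any(!is.finite(a)))
               msg <- c(msg, sprintf("window '%s' has non-finite counts", w))
           }
           if (is.null(msg)) TRUE else msg
         })

#' VoiSet: volumes of interest for image-quality scoring
#'
#' @slot sphereMasks named list of logical 3D arrays, one per sphere, pairwise
#'   disjoint.
#' @slot backgroundMask logical 3D array, disjoint from all sphere masks.
#' @slot trueConc named numeric: true activity concentration (MBq/ml) per
#'   sphere plus element "background".
#' @exportClass VoiSet
setClass("VoiSet",
         representation(sphereMasks = "list", backgroundMask = "array",
                        trueConc = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (length(object@sphereMasks) == 0L)
             msg <- c(msg, "no sphere masks")
           tot <- array(0L, dim(object@backgroundMask))
           for (m in object@sphereMasks) {
             if (!any(m)) msg <- c(msg, "empty sphere mask")
             tot <- tot + m
           }
           if (any(tot > 1L)) msg <- c(msg, "sphere masks overlap")
           if (any(tot & object@backgroundMask))
             msg <- c(msg, "sphere masks overlap the background mask")
           if (!any(object@backgroundMask)) msg <- c(msg, "empty background mask")
           if (!"background" %in% names(object@trueConc))
             msg <- c(msg, "trueConc must contain 'background'")
           if (is.null(msg)) TRUE else msg
         })

#' SigmoidFit: least-squares sigmoid fit of a CRC curve
#'
#' Model S(x) = a / (1 + exp(-b (x - c))) - d with the plateau fixed at
#' a = 1 (contrast recovery tends to 1 for large spheres); b, c, d are
#' estimated by least squares.
#'
#' @slot a fixed plateau, always 1.
#' @slot b slope (1 / x-units).
#' @slot c midpoint, in sphere-diameter/FWHM units.
#' @slot d offset.
#' @slot residualSS residual sum of squares of the fit.
#' @slot fitted fitted values at the input x.
#' @exportClass SigmoidFit
setClass("SigmoidFit",
         representation(a = "numeric", b = "numeric", c = "numeric",
                        d = "numeric", residualSS = "numeric",
                        fitted = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (!identical(object@a, 1)) msg <- c(msg, "'a' is fixed at 1")
           if (object@residualSS < 0) msg <- c(msg, "negative residual SS")
           if (is.null(msg)) TRUE else msg
         })

#' DoseReport: voxel dose map with compartment summaries
#'
#' @slot doseMap 3D numeric array, Gy, non-negative.
#' @slot summary data.frame with one row per compartment: `compartment`,
#'   `mass_g`, `meanDose_Gy`, `fraction_ge_150Gy` (tumour criterion),
#'   `fraction_0_50Gy` (non-tumoral liver criterion).
#' @slot params list of the dosimetry parameters used.
#' @exportClass DoseReport
setClass("DoseReport",
         representation(doseMap = "array", summary = "data.frame",
                        params = "list"),
         validity = function(object) {
           msg <- NULL
           if (any(object@doseMap < 0)) msg <- c(msg, "negative dose")
           fr <- unlist(object@summary[, grep("^fraction",
                                              names(object@summary))])
           if (length(fr) && any(fr < -1e-12 | fr > 1 + 1e-12))
             msg <- c(msg, "fractions must lie in [0,1]")
           if (is.null(msg)) TRUE else msg
         })

## ---- small parameter holders ----

#' OSEM reconstruction parameters
#'
#' Defaults follow the study protocol: 10 iterations with 8 subsets.
#'
#' @slot nIterations number of full iterations (>= 1).
#' @slot nSubsets number of angular subsets; must divide the number of
#'   projections.
#' @slot usePsf logical; model the distance-dependent PSF inside the
#'   projector (resolution recovery).
#' @slot epsilon small positive stabiliser added to forward projections.
#' @exportClass OsemParams
setClass("OsemParams",
         representation(nIterations = "integer", nSubsets = "integer",
                        usePsf = "logical", epsilon = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (object@nIterations < 1L) msg <- c(msg, "'nIterations' >= 1 required")
           if (object@nSubsets < 1L) msg <- c(msg, "'nSubsets' >= 1 required")
           if (object@epsilon <= 0) msg <- c(msg, "'epsilon' must be > 0")
           if (is.null(msg)) TRUE else msg
         })

#' @describeIn OsemParams-class Constructor.
#' @param nIterations,nSubsets,usePsf,epsilon see slots.
#' @return An [OsemParams-class] object.
#' @export
osemParams <- function(nIterations = 10L, nSubsets = 8L, usePsf = FALSE,
                       epsilon = 1e-12) {
  new("OsemParams", nIterations = as.integer(nIterations),
      nSubsets = as.integer(nSubsets), usePsf = isTRUE(usePsf),
      epsilon = as.numeric(epsilon))
}

#' Butterworth post-filter parameters
#'
#' Defaults follow the study protocol (cutoff 0.25 cycles/pixel, order 1.5);
#' the filter is applied for visualisation only.
#'
#' @slot cutoff cycles/pixel, in (0, 0.5].
#' @slot order filter order (> 0).
#' @exportClass ButterworthParams
setClass("ButterworthParams",
         representation(cutoff = "numeric", order = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (object@cutoff <= 0 || object@cutoff > 0.5)
             msg <- c(msg, "'cutoff' must be in (0, 0.5] cycles/pixel")
           if (object@order <= 0) msg <- c(msg, "'order' must be > 0")
           if (is.null(msg)) TRUE else msg
         })

#' @describeIn ButterworthParams-class Constructor.
#' @param cutoff,order see slots.
#' @return A [ButterworthParams-class] object.
#' @export
butterworthParams <- function(cutoff = 0.25, order = 1.5) {
  new("ButterworthParams", cutoff = as.numeric(cutoff),
      order = as.numeric(order))
}

#' Dual-energy-window correction parameters
#'
#' @slot k dimensionless scale on the downscatter window; k = 1 is the
#'   established choice for Ho-166.
#' @exportClass DewParams
setClass("DewParams", representation(k = "numeric"),
         validity = function(object) {
           if (object@k < 0) "'k' must be >= 0" else TRUE
         })

#' @describeIn DewParams-class Constructor.
#' @param k downscatter scaling factor.
#' @return A [DewParams-class] object.
#' @export
dewParams <- function(k = 1.0) new("DewParams", k = as.numeric(k))

#' Radioactive decay parameters
#'
#' @slot halfLife hours; default is the Ho-166 half-life, 26.8 h.
#' @exportClass DecayParams
setClass("DecayParams", representation(halfLife = "numeric"),
         validity = function(object) {
           if (object@halfLife <= 0) "'halfLife' must be > 0" else TRUE
         })

#' @describeIn DecayParams-class Constructor.
#' @param halfLife hours.
#' @return A [DecayParams-class] object.
#' @export
decayParams <- function(halfLife = 26.8)
  new("DecayParams", halfLife = as.numeric(halfLife))

#' Local-dose-deposition dosimetry parameters
#'
#' @slot administeredActivity GBq administered (> 0).
#' @slot doseCoefficient J/GBq: energy locally deposited per unit administered
#'   activity after complete decay. Default 15.87 J/GBq for Ho-166.
#' @slot tissueDensity g/ml; 1.0 for phantom water, 1.06 is typical for liver.
#' @exportClass DoseParams
setClass("DoseParams",
         representation(administeredActivity = "numeric",
                        doseCoefficient = "numeric",
                        tissueDensity = "numeric"),
         validity = function(object) {
           if (object@administeredActivity <= 0 || object@doseCoefficient <= 0 ||
               object@tissueDensity <= 0)
             "all dose parameters must be > 0" else TRUE
         })

#' @describeIn DoseParams-class Constructor.
#' @param administeredActivity,doseCoefficient,tissueDensity see slots.
#' @return A [DoseParams-class] object.
#' @export
doseParams <- function(administeredActivity, doseCoefficient = 15.87,
                       tissueDensity = 1.0) {
  new("DoseParams", administeredActivity = as.numeric(administeredActivity),
      doseCoefficient = as.numeric(doseCoefficient),
      tissueDensity = as.numeric(tissueDensity))
}
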