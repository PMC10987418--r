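## Local-dose-deposition voxel dosimetry, compartment summaries, activity
## planning and the paired statistical comparison of correction methods.

#' Local-dose-deposition voxel dose map
#'
#' Under the local-deposition model every voxel absorbs, locally, a share of
#' the total deposited energy proportional to its reconstructed activity:
#' dose_v \[Gy\] = A * kappa * (counts_v / total counts) * 1000 / mass_v \[g\],
#' with A the administered activity (GBq) and kappa the locally deposited
#' energy per administered GBq after complete decay (J/GBq). Reconstructed
#' counts enter only through their relative distribution, so any global
#' calibration factor cancels.
#'
#' @param activityVolume non-negative 3D array (reconstructed counts or any
#'   activity-proportional voxel values).
#' @param params a [DoseParams-class].
#' @param voxelMass g per voxel: scalar or array; default derived from
#'   `voxelVolume_ml * tissueDensity` when `voxelVolume_ml` is given.
#' @param voxelVolume_ml voxel volume in ml, used with the params' tissue
#'   density when `voxelMass` is missing.
#' @return 3D array of absorbed dose in Gy.
#' @export
lddDoseMap <- function(activityVolume, params, voxelMass = NULL,
                       voxelVolume_ml = NULL) {
  stopifnot(is(params, "DoseParams"))
  if (any(activityVolume < 0)) stop("negative activity values", call. = FALSE)
  tot <- sum(activityVolume)
  if (tot <= 0) stop("zero total counts; dose undefined", call. = FALSE)
  if (is.null(voxelMass)) {
    if (is.null(voxelVolume_ml))
      stop("supply 'voxelMass' (g) or 'voxelVolume_ml'", call. = FALSE)
    voxelMass <- voxelVolume_ml * params@tissueDensity
  }
  if (any(voxelMass <= 0)) stop("voxel mass must be > 0", call. = FALSE)
  energyJ <- params@administeredActivity * params@doseCoefficient *
    activityVolume / tot
  energyJ * 1000 / voxelMass
}

#' Compartment dose summary
#'
#' Mass-weighted mean dose and dose-volume-histogram fractions for the
#' tumour and non-tumoral-liver (NTL) compartments: the tumour fraction
#' receiving at least 150 Gy and the NTL fraction receiving between 0
#' (inclusive) and 50 Gy (exclusive). With equal-mass voxels the fractions
#' reduce to voxel counting.
#'
#' @param doseMap 3D array, Gy.
#' @param tumorMask,ntlMask disjoint non-empty logical arrays.
#' @param voxelMass g per voxel, scalar or array.
#' @param params optional [DoseParams-class], recorded in the report.
#' @return A [DoseReport-class]; `doseSummary()` has one row per compartment
#'   with `mass_g`, `meanDose_Gy`, `fraction_ge_150Gy` and `fraction_0_50Gy`.
#' @export
compartmentStats <- function(doseMap, tumorMask, ntlMask, voxelMass = 1,
                             params = NULL) {
  if (!any(tumorMask) || !any(ntlMask))
    stop("empty compartment mask", call. = FALSE)
  if (any(tumorMask & ntlMask))
    stop("tumour and NTL masks overlap", call. = FALSE)
  if (length(voxelMass) == 1L) voxelMass <- array(voxelMass, dim(doseMap))
  oneComp <- function(mask) {
    d <- doseMap[mask]; m <- voxelMass[mask]
    M <- sum(m)
    c(mass_g = M,
      meanDose_Gy = sum(d * m) / M,
      fraction_ge_150Gy = sum(m[d >= 150]) / M,
      fraction_0_50Gy = sum(m[d >= 0 & d < 50]) / M)
  }
  summ <- as.data.frame(rbind(tumor = oneComp(tumorMask),
                              ntl = oneComp(ntlMask)))
  summ <- cbind(compartment = rownames(summ), summ)
  rownames(summ) <- NULL
  new("DoseReport", doseMap = doseMap, summary = summ,
      params = if (is.null(params)) list() else
        list(administeredActivity = params@administeredActivity,
             doseCoefficient = params@doseCoefficient,
             tissueDensity = params@tissueDensity))
}

#' Plan the activity to administer for a target tumour dose
#'
#' Linear planning: planned activity = target dose / tumour dose per unit
#' activity. The lung constraint (30 Gy in a single treatment, 50 Gy
#' cumulative over multiple treatments) is checked at the planned activity
#' and violations are reported, never silently capped.
#'
#' @param dosePerUnitActivity Gy/GBq in the tumour (> 0).
#' @param targetDose Gy (the clinical planning range is 169-300 Gy).
#' @param lungDosePerUnit Gy/GBq in the lung at the same administration.
#' @param priorLungDose Gy already delivered to the lung in earlier
#'   treatments.
#' @return list with `planned_GBq`, `lungDose_Gy`, `lungSingleOK` (<= 30 Gy),
#'   `lungCumulativeOK` (prior + planned <= 50 Gy) and `feasible`.
#' @export
planActivity <- function(dosePerUnitActivity, targetDose,
                         lungDosePerUnit = 0, priorLungDose = 0) {
  if (dosePerUnitActivity <= 0)
    stop("'dosePerUnitActivity' must be > 0", call. = FALSE)
  planned <- targetDose / dosePerUnitActivity
  lung <- planned * lungDosePerUnit
  singleOK <- lung <= 30
  cumulOK <- priorLungDose + lung <= 50
  list(planned_GBq = planned, lungDose_Gy = lung,
       lungSingleOK = singleOK, lungCumulativeOK = cumulOK,
       feasible = singleOK && cumulOK)
}

#' Paired t-test
#'
#' Two-sided paired t-test on per-treatment values from two correction
#' methods: t = mean(d) / (sd(d) / sqrt(n)) with d = x - y and n - 1 degrees
#' of freedom. The significance threshold reported is 0.05. If every
#' difference is exactly zero the statistic is defined as 0 with p = 1; a
#' degenerate case of identical non-zero differences (zero variance, nonzero
#' mean) is an error.
#'
#' @param x,y equal-length numeric vectors (n >= 2), pairwise matched.
#' @return list with `t`, `df`, `p`, `meanDifference`, `significant`.
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  md <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (md == 0) {
      t <- 0; p <- 1
    } else stop("zero variance of differences with nonzero mean",
                call. = FALSE)
  } else {
    t <- md / (s / sqrt(n))
    p <- 2 * pt(-abs(t), df = n - 1)
  }
  list(t = t, df = n - 1L, p = p, meanDifference = md,
       significant = p <= 0.05)
}
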