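## Digital Jaszczak-style phantom construction and decay bookkeeping.

## Photon mass attenuation coefficients mu/rho (cm^2/g), published standard
## reference tables, 50-150 keV. Water density 1.0 g/ml, PMMA 1.19 g/ml.
MU_TABLE_KEV <- c(50, 60, 80, 100, 150)
MU_RHO_WATER <- c(0.2269, 0.2059, 0.1837, 0.1707, 0.1505)
MU_RHO_PMMA  <- c(0.2088, 0.1924, 0.1751, 0.1641, 0.1456)
DENSITY_WATER <- 1.00
DENSITY_PMMA <- 1.19

## log-log interpolation of a mass-attenuation table at `energy` keV
muAt <- function(energy, muRho, density) {
  if (energy < min(MU_TABLE_KEV) || energy > max(MU_TABLE_KEV))
    stop(sprintf("energy %.1f keV outside tabulated range [%g, %g] keV",
                 energy, min(MU_TABLE_KEV), max(MU_TABLE_KEV)), call. = FALSE)
  lm <- stats::approx(log(MU_TABLE_KEV), log(muRho), xout = log(energy))$y
  exp(lm) * density
}

#' Specify a fillable sphere insert
#'
#' @param center numeric(3), mm, sphere centre in world coordinates.
#' @param innerDiameter mm (> 0), diameter of the fillable cavity.
#' @param wallThickness mm (>= 0) of the plastic shell.
#' @param activityConc MBq/ml (>= 0) in the cavity.
#' @return A one-row data.frame; `rbind` rows to build a sphere set.
#' @export
sphereSpec <- function(center, innerDiameter, wallThickness = 2,
                       activityConc = 0) {
  stopifnot(length(center) == 3, innerDiameter > 0, wallThickness >= 0,
            activityConc >= 0)
  data.frame(cx = center[1], cy = center[2], cz = center[3],
             innerDiameter = innerDiameter, wallThickness = wallThickness,
             activityConc = activityConc)
}

#' The six-sphere set of the Jaszczak Pro-NM phantom
#'
#' Fillable spheres with inner diameters 9.9, 12.4, 15.4, 19.8, 24.8 and
#' 31.3 mm and a 2 mm wall, placed on a ring in one transverse plane
#' (mid-height by default), smallest sphere first.
#'
#' @param activityConc MBq/ml filled into every sphere (they are filled from
#'   one stock solution, so all spheres share one concentration).
#' @param ringRadius mm, radius of the circle the sphere centres sit on.
#' @param planeZ mm, axial coordinate of the sphere-centre plane.
#' @return data.frame of sphere specifications (see [sphereSpec()]).
#' @export
jaszczakSpheres <- function(activityConc = 29 / 31.5, ringRadius = 60,
                            planeZ = 0) {
  d <- c(9.9, 12.4, 15.4, 19.8, 24.8, 31.3)
  ang <- (seq_along(d) - 1) * 2 * pi / length(d)
  do.call(rbind, lapply(seq_along(d), function(i)
    sphereSpec(center = c(ringRadius * cos(ang[i]), ringRadius * sin(ang[i]),
                          planeZ),
               innerDiameter = d[i], wallThickness = 2,
               activityConc = activityConc)))
}

#' Build a digital Jaszczak-style cylinder phantom
#'
#' Voxelizes a water-filled cylinder (inner diameter 206 mm, inner height
#' 186 mm, 7 mm PMMA wall by default) with optional fillable sphere inserts,
#' assigning region labels, activity concentration and linear attenuation by
#' voxel-centre membership. The cylinder axis is the grid z axis through the
#' world origin; sphere positions are world coordinates (mm).
#'
#' Region labels: 0 air, 1 background, 2..(1+n) spheres in list order,
#' 8 wall (cylinder shell, end plates and sphere shells).
#'
#' @param grid a [GridSpec-class]; the default 128-cube at 4 mm covers the
#'   phantom with margin.
#' @param spheres data.frame of sphere inserts ([sphereSpec()] /
#'   [jaszczakSpheres()] rows), or NULL for a uniform cylinder.
#' @param backgroundConc MBq/ml in the background compartment.
#' @param innerDiameter,innerHeight,wallThickness mm, cylinder dimensions.
#' @param energy keV at which the attenuation map is evaluated (the Ho-166
#'   photopeak by default).
#' @return A [VoxelPhantom-class]. `regionTable()` on the result reports, per
#'   region, the analytic volume implied by the defining dimensions next to
#'   the voxelized volume.
#' @export
buildJaszczak <- function(grid = gridSpec(), spheres = jaszczakSpheres(),
                          backgroundConc = 312 / 6200,
                          innerDiameter = 206, innerHeight = 186,
                          wallThickness = 7, energy = 80.6) {
  stopifnot(is(grid, "GridSpec"), backgroundConc >= 0)
  R <- innerDiameter / 2
  H <- innerHeight
  ns <- if (is.null(spheres)) 0L else nrow(spheres)
  if (ns > 6L)
    stop("at most 6 sphere inserts supported (labels 2..7)", call. = FALSE)

  if (ns > 0) {
    outerR <- (spheres$innerDiameter / 2 + spheres$wallThickness)
    rad <- sqrt(spheres$cx^2 + spheres$cy^2)
    if (any(rad + outerR > R | abs(spheres$cz) + outerR > H / 2))
      stop("sphere outside the inner cylinder", call. = FALSE)
    if (ns > 1) {
      for (i in 1:(ns - 1)) for (j in (i + 1):ns) {
        dij <- sqrt(sum((unlist(spheres[i, c("cx", "cy", "cz")]) -
                         unlist(spheres[j, c("cx", "cy", "cz")]))^2))
        if (dij < outerR[i] + outerR[j])
          stop(sprintf("spheres %d and %d overlap", i, j), call. = FALSE)
      }
    }
  }

  cc <- axisCoords(grid)
  nx <- grid@shape[1]; ny <- grid@shape[2]; nz <- grid@shape[3]
  ## squared radial distance from the cylinder axis, one transverse plane
  r2 <- outer(cc[[1]]^2, cc[[2]]^2, "+")
  inCyl2d <- r2 <= R^2
  inWall2d <- r2 <= (R + wallThickness)^2
  labels <- array(0L, grid@shape)
  zin <- abs(cc[[3]]) <= H / 2
  zwall <- abs(cc[[3]]) <= H / 2 + wallThickness
  for (k in seq_len(nz)) {
    if (zwall[k]) labels[, , k][inWall2d] <- 8L
    if (zin[k]) labels[, , k][inCyl2d] <- 1L
  }

  activity <- array(0, grid@shape)
  activity[labels == 1L] <- backgroundConc

  if (ns > 0) {
    for (i in seq_len(ns)) {
      s <- spheres[i, ]
      d2 <- outer(outer((cc[[1]] - s$cx)^2, (cc[[2]] - s$cy)^2, "+"),
                  (cc[[3]] - s$cz)^2, "+")
      shell <- d2 <= (s$innerDiameter / 2 + s$wallThickness)^2
      core <- d2 <= (s$innerDiameter / 2)^2
      labels[shell] <- 8L
      labels[core] <- 1L + i
      activity[shell] <- 0
      activity[core] <- s$activityConc
    }
  }

  mu <- muForLabels(labels, energy)

  vml <- voxelVolume(grid)
  sphereVol <- if (ns > 0) pi / 6 * spheres$innerDiameter^3 / 1000 else numeric(0)
  sphereOuter <- if (ns > 0)
    pi / 6 * (spheres$innerDiameter + 2 * spheres$wallThickness)^3 / 1000 else numeric(0)
  cylVol <- pi * R^2 * H / 1000
  wallVol <- (pi * (R + wallThickness)^2 * (H + 2 * wallThickness) -
              pi * R^2 * H) / 1000 + sum(sphereOuter - sphereVol)
  regions <- data.frame(
    region = c("background", if (ns > 0) sprintf("sphere_%02.1fmm",
                                                 spheres$innerDiameter),
               "wall"),
    label = c(1L, if (ns > 0) 1L + seq_len(ns), 8L),
    analyticVolume_ml = c(cylVol - sum(sphereOuter), sphereVol, wallVol),
    conc_MBq_ml = c(backgroundConc, if (ns > 0) spheres$activityConc, 0))
  regions$voxelVolume_ml <- vapply(regions$label,
                                   function(l) sum(labels == l) * vml, 0)
  new("VoxelPhantom", grid = grid, activity = activity, mu = mu,
      labels = labels, regions = regions)
}

muForLabels <- function(labels, energy) {
  mu <- array(0, dim(labels))
  mu[labels >= 1L & labels <= 7L] <- muAt(energy, MU_RHO_WATER, DENSITY_WATER)
  mu[labels == 8L] <- muAt(energy, MU_RHO_PMMA, DENSITY_PMMA)
  mu
}

#' Attenuation map of a phantom at a given photon energy
#'
#' Assigns water-equivalent linear attenuation to the background and sphere
#' compartments, PMMA to the walls and zero to air, interpolating embedded
#' standard mass-attenuation tables (log-log) at the requested energy.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param energy keV, within the tabulated 50-150 keV range.
#' @return 3D array of linear attenuation coefficients (1/cm).
#' @export
attenuationMap <- function(phantom, energy = 80.6) {
  stopifnot(is(phantom, "VoxelPhantom"))
  muForLabels(phantom@labels, energy)
}

#' Radioactive decay
#'
#' `decayActivity(A, t)` returns `A * 2^(-t / halfLife)`.
#'
#' @param activity MBq at time zero (vectorised).
#' @param elapsed hours since time zero (vectorised, >= 0).
#' @param params a [DecayParams-class]; default Ho-166 (26.8 h half-life).
#' @return Decayed activity in MBq.
#' @export
decayActivity <- function(activity, elapsed, params = decayParams()) {
  stopifnot(is(params, "DecayParams"))
  if (any(elapsed < 0)) stop("'elapsed' must be >= 0", call. = FALSE)
  activity * 2^(-elapsed / params@halfLife)
}
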