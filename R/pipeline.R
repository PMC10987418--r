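## Pipeline driver: configuration, stage commands and the end-to-end run.

defaultConfig <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    sensitivity = DEFAULT_SENSITIVITY,
    phantom = list(gridShape = c(128L, 128L, 128L), voxelSize = 4,
                   backgroundConc = 312 / 6200, sphereConc = 29 / 31.5,
                   ringRadius = 60),
    geometry = list(nProjections = 120L, angleSpan = 360,
                    timePerProjection = 30, orbitRadius = 300,
                    startTime = 0),
    psf = list(fwhmIntrinsic = 4, fwhmSlope = 0.55),
    spectrum = list(rateScale = c(W1 = 0.30, W2 = 1.0, W3 = 0.25,
                                  W4 = 0.25)),
    kernels = list(photopeakUnscattered = 0.6),
    correction = list(method = "tew", k = 1.0, clamp = TRUE),
    osem = list(nIterations = 10L, nSubsets = 8L, usePsf = FALSE,
                epsilon = 1e-12),
    butterworth = list(cutoff = 0.25, order = 1.5,
                       applyBeforeMetrics = FALSE),
    metrics = list(erosionMargin = 1L, bgRadius = 25, bgHeight = 40),
    dose = list(administeredActivity = 0.341, doseCoefficient = 15.87,
                tissueDensity = 1.0))
}

mergeConfig <- function(base, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(base))
      stop(sprintf("unknown configuration key '%s%s'", path, k),
           call. = FALSE)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]]))
        stop(sprintf("configuration key '%s%s' must be a mapping", path, k),
             call. = FALSE)
      base[[k]] <- mergeConfig(base[[k]], user[[k]], paste0(path, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Pipeline configuration
#'
#' Builds a fully resolved configuration list by overlaying user settings on
#' the defaults (the study's phantom, acquisition protocol, spectrum model,
#' window table and reconstruction parameters). Unknown keys are rejected
#' with the offending key named.
#'
#' @param ... named settings, possibly nested lists (e.g.
#'   `osem = list(nIterations = 5)`).
#' @param config optionally a complete user list instead of `...`.
#' @return the resolved configuration list.
#' @export
pipelineConfig <- function(..., config = NULL) {
  user <- if (is.null(config)) list(...) else config
  mergeConfig(defaultConfig(), user)
}

#' @describeIn pipelineConfig Read a YAML configuration file and resolve it
#'   against the defaults.
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  pipelineConfig(config = yaml::read_yaml(path))
}

configObjects <- function(cfg) {
  gs <- cfg$phantom$gridShape
  grid <- gridSpec(gs, cfg$phantom$voxelSize)
  spheres <- jaszczakSpheres(activityConc = cfg$phantom$sphereConc,
                             ringRadius = cfg$phantom$ringRadius)
  geom <- acquisitionGeometry(
    nProjections = cfg$geometry$nProjections,
    angleSpan = cfg$geometry$angleSpan,
    timePerProjection = cfg$geometry$timePerProjection,
    detectorMatrix = c(gs[1], gs[3]),
    pixelSize = cfg$phantom$voxelSize,
    orbitRadius = cfg$geometry$orbitRadius,
    startTime = cfg$geometry$startTime)
  psf <- psfModel(cfg$psf$fwhmIntrinsic, cfg$psf$fwhmSlope)
  model <- spectrumComponentModel(rateScale = unlist(cfg$spectrum$rateScale))
  kern <- scatterKernels(psf = psf, orbitRadius = cfg$geometry$orbitRadius,
                         photopeakUnscattered = cfg$kernels$photopeakUnscattered)
  list(grid = grid, spheres = spheres, geom = geom, psf = psf,
       model = model, kernels = kern)
}

#' Pipeline stage commands
#'
#' Thin drivers over the package's functions, mirroring the pipeline stages:
#' `cmdSimulate` builds the phantom and simulates the four-window
#' acquisition plus the scatter-free reference; `cmdCorrect` applies a
#' scatter correction; `cmdReconstruct` runs OSEM; `cmdMetrics` scores
#' CRC/CNR and fits the sigmoid curves; `cmdDose` computes the
#' local-deposition dose report; `cmdStats` compares two methods' paired
#' per-lesion values. Each stage records provenance; [runPipeline()] chains
#' them.
#'
#' @param config a resolved configuration from [pipelineConfig()].
#' @param outdir optional directory; when given, stages write their bundles
#'   and tables there.
#' @return `cmdSimulate`: list with `phantom`, `mu`, `primary`,
#'   `acquisition` and `scatterFree`.
#' @name pipeline-stages
#' @export
cmdSimulate <- function(config = pipelineConfig(), outdir = NULL) {
  ob <- configObjects(config)
  phantom <- buildJaszczak(ob$grid, ob$spheres,
                           backgroundConc = config$phantom$backgroundConc)
  mu <- attenuationMap(phantom)
  primary <- forwardProject(phantom, ob$geom, psf = ob$psf, mu = mu,
                            sensitivity = config$sensitivity)
  acq <- synthesizeAcquisition(primary, ob$model, ob$kernels,
                               seed = config$seed)
  sf <- realizeCounts(primary, seed = config$seed + 1L)
  if (!is.null(outdir)) {
    writePhantom(phantom, outdir)
    writeProjectionSet(acq, outdir, "acq")
    writeProjectionSet(sf, outdir, "scatterfree")
    jsonlite::write_json(list(seed = config$seed,
                              configHash = objectHash(config)),
                         file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(phantom = phantom, mu = mu, primary = primary,
                 acquisition = acq, scatterFree = sf))
}

#' @rdname pipeline-stages
#' @param ps a [ProjectionSet-class].
#' @param method "tew", "dew" or "none".
#' @export
cmdCorrect <- function(ps, method = "tew", config = pipelineConfig()) {
  correctProjections(ps, method = method,
                     params = dewParams(config$correction$k),
                     clamp = isTRUE(config$correction$clamp))
}

#' @rdname pipeline-stages
#' @param mu attenuation array or NULL.
#' @export
cmdReconstruct <- function(ps, mu = NULL, config = pipelineConfig()) {
  ob <- configObjects(config)
  params <- osemParams(config$osem$nIterations, config$osem$nSubsets,
                       config$osem$usePsf, config$osem$epsilon)
  osemReconstruct(ps, mu = mu, params = params, psf = ob$psf,
                  grid = ob$grid)
}

#' @rdname pipeline-stages
#' @param volumes named list of reconstructed volumes (one per method).
#' @param phantom the [VoxelPhantom-class] the volumes reconstruct.
#' @export
cmdMetrics <- function(volumes, phantom, config = pipelineConfig()) {
  ob <- configObjects(config)
  vois <- makeVois(phantom, erosionMargin = config$metrics$erosionMargin,
                   bgRadius = config$metrics$bgRadius,
                   bgHeight = config$metrics$bgHeight)
  fwhm <- fwhmAt(ob$psf, config$geometry$orbitRadius / 10)
  diam <- ob$spheres$innerDiameter
  rows <- list(); fits <- list()
  for (m in names(volumes)) {
    v <- volumes[[m]]
    if (isTRUE(config$butterworth$applyBeforeMetrics))
      v <- butterworthFilter(v, butterworthParams(config$butterworth$cutoff,
                                                  config$butterworth$order))
    crcV <- crc(v, vois)
    cnrV <- cnr(v, vois)
    rows[[m]] <- data.frame(method = m,
                            sphere = names(vois@sphereMasks),
                            diameter_mm = diam,
                            x = diam / fwhm,
                            crc = unname(crcV), cnr = unname(cnrV))
    fit <- tryCatch(fitSigmoid(diam / fwhm, unname(crcV)),
                    error = function(e) NULL)
    fits[[m]] <- if (is.null(fit)) NULL else
      list(a = 1, b = fit@b, c = fit@c, d = fit@d,
           residualSS = fit@residualSS)
  }
  list(table = do.call(rbind, rows), fits = fits, vois = vois, fwhm = fwhm)
}

#' @rdname pipeline-stages
#' @param volume a reconstructed volume.
#' @export
cmdDose <- function(volume, phantom, config = pipelineConfig()) {
  dp <- doseParams(config$dose$administeredActivity,
                   config$dose$doseCoefficient,
                   config$dose$tissueDensity)
  vml <- voxelVolume(phantom)
  dm <- lddDoseMap(volume, dp, voxelVolume_ml = vml)
  lab <- regionLabels(phantom)
  compartmentStats(dm, tumorMask = lab >= 2L & lab <= 7L,
                   ntlMask = lab == 1L,
                   voxelMass = vml * config$dose$tissueDensity, params = dp)
}

#' @rdname pipeline-stages
#' @param valuesA,valuesB paired per-lesion (or per-treatment) values for
#'   two methods.
#' @param labelA,labelB method names for the comparison table.
#' @param criterion name of the compared quantity.
#' @export
cmdStats <- function(valuesA, valuesB, labelA = "DEW", labelB = "TEW",
                     criterion = "tumor_dose") {
  tt <- pairedTTest(valuesA, valuesB)
  data.frame(criterion = criterion,
             meanA = mean(valuesA), sdA = sd(valuesA),
             meanB = mean(valuesB), sdB = sd(valuesB),
             methodA = labelA, methodB = labelB,
             t = tt$t, df = tt$df, p = tt$p,
             significant = tt$significant)
}

#' Run the full phantom study pipeline
#'
#' Simulates the phantom acquisition, applies every correction arm
#' (scatter-free reference, uncorrected, DEW, TEW), reconstructs each with
#' the same OSEM protocol, scores CRC/CNR with sigmoid fits, and computes
#' the local-deposition dose report per arm with a paired DEW-vs-TEW
#' comparison over the sphere ("tumour") doses. With `dryRun = TRUE` the
#' resolved configuration is printed and nothing is computed.
#'
#' @param config resolved configuration ([pipelineConfig()]).
#' @param outdir optional output directory for volumes, tables and sidecars.
#' @param dryRun print the resolved configuration and exit.
#' @param verbose print stage progress to stderr.
#' @return list with `volumes`, `metrics`, `doseReports`, `sphereDoses`,
#'   `stats`, `simulation` and `config`.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = config$outdir,
                        dryRun = FALSE, verbose = FALSE) {
  if (dryRun) {
    cat(yaml::as.yaml(config))
    return(invisible(config))
  }
  say <- function(...) if (verbose) message(...)
  say("simulate")
  sim <- cmdSimulate(config, outdir = outdir)
  arms <- list(
    scatter_free = sim$scatterFree,
    uncorrected = cmdCorrect(sim$acquisition, "none", config),
    dew = cmdCorrect(sim$acquisition, "dew", config),
    tew = cmdCorrect(sim$acquisition, "tew", config))
  volumes <- list()
  for (m in names(arms)) {
    say("reconstruct ", m)
    volumes[[m]] <- cmdReconstruct(arms[[m]], mu = sim$mu, config = config)
  }
  say("metrics")
  met <- cmdMetrics(volumes, sim$phantom, config)
  say("dose")
  doseReports <- lapply(volumes, cmdDose, phantom = sim$phantom,
                        config = config)
  ## paired per-sphere mean doses, DEW vs TEW
  sphereDose <- function(v) {
    dp <- doseParams(config$dose$administeredActivity,
                     config$dose$doseCoefficient, config$dose$tissueDensity)
    dm <- lddDoseMap(v, dp, voxelVolume_ml = voxelVolume(sim$phantom))
    lab <- regionLabels(sim$phantom)
    vapply(sort(unique(lab[lab >= 2L & lab <= 7L])),
           function(l) mean(dm[lab == l]), 0)
  }
  sphereDoses <- lapply(volumes[c("dew", "tew")], sphereDose)
  stats <- cmdStats(sphereDoses$dew, sphereDoses$tew,
                    criterion = "sphere_mean_dose_Gy")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(met$table, file.path(outdir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(met$fits, file.path(outdir, "sigmoid_fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    doseTab <- do.call(rbind, lapply(names(doseReports), function(m)
      cbind(method = m, doseSummary(doseReports[[m]]))))
    utils::write.csv(doseTab, file.path(outdir, "dose_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(stats, file.path(outdir, "stats.csv"),
                     row.names = FALSE)
    for (m in names(volumes))
      writeVolume(volumes[[m]],
                  file.path(outdir, paste0("recon_", m, ".nii.gz")),
                  voxelSize = config$phantom$voxelSize,
                  meta = list(method = m, seed = config$seed,
                              configHash = objectHash(config)))
  }
  invisible(list(volumes = volumes, metrics = met,
                 doseReports = doseReports, sphereDoses = sphereDoses,
                 stats = stats, simulation = sim, config = config))
}
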