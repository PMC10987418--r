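## On-disk bundles: NIfTI volumes plus JSON sidecars for geometry, regions
## and provenance.

gridToList <- function(grid) {
  list(shape = as.integer(grid@shape), voxelSize = grid@voxelSize,
       origin = grid@origin)
}

gridFromList <- function(l) {
  gridSpec(shape = l$shape, voxelSize = l$voxelSize, origin = l$origin)
}

geomToList <- function(g) {
  list(nProjections = g@nProjections, angleSpan = g@angleSpan,
       timePerProjection = g@timePerProjection,
       detectorMatrix = g@detectorMatrix, pixelSize = g@pixelSize,
       orbitRadius = g@orbitRadius, startTime = g@startTime,
       rotation = "counter-clockwise, projection 1 at 0 degrees (anterior)")
}

geomFromList <- function(l) {
  acquisitionGeometry(nProjections = l$nProjections, angleSpan = l$angleSpan,
                      timePerProjection = l$timePerProjection,
                      detectorMatrix = l$detectorMatrix,
                      pixelSize = l$pixelSize, orbitRadius = l$orbitRadius,
                      startTime = l$startTime)
}

#' Write / read a phantom bundle
#'
#' Stores the activity, attenuation and label volumes as NIfTI files plus a
#' JSON sidecar holding the grid specification and the region table.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return `writePhantom` returns the sidecar path invisibly; `readPhantom`
#'   returns the [VoxelPhantom-class].
#' @export
writePhantom <- function(phantom, dir, prefix = "phantom") {
  stopifnot(is(phantom, "VoxelPhantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vd <- phantom@grid@voxelSize
  p <- function(s) file.path(dir, paste0(prefix, "_", s, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom@activity, pixdim = vd), p("activity"))
  RNifti::writeNifti(RNifti::asNifti(phantom@mu, pixdim = vd), p("mu"))
  RNifti::writeNifti(RNifti::asNifti(phantom@labels * 1, pixdim = vd), p("labels"))
  side <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(grid = gridToList(phantom@grid),
                            regions = phantom@regions),
                       side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(side)
}

#' @rdname writePhantom
#' @export
readPhantom <- function(dir, prefix = "phantom") {
  side <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  grid <- gridFromList(side$grid)
  p <- function(s) file.path(dir, paste0(prefix, "_", s, ".nii.gz"))
  rd <- function(f) {
    a <- as.array(RNifti::readNifti(f))
    attributes(a) <- list(dim = dim(a))
    a
  }
  lab <- rd(p("labels"))
  new("VoxelPhantom", grid = grid, activity = rd(p("activity")),
      mu = rd(p("mu")), labels = array(as.integer(round(lab)), dim(lab)),
      regions = as.data.frame(side$regions))
}

#' Write / read a projection-set bundle
#'
#' One NIfTI stack per energy window plus a JSON sidecar with the
#' acquisition geometry, window table, component tallies and provenance
#' chain.
#'
#' @param ps a [ProjectionSet-class].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return `writeProjectionSet` returns the sidecar path invisibly;
#'   `readProjectionSet` returns the [ProjectionSet-class].
#' @export
writeProjectionSet <- function(ps, dir, prefix = "proj") {
  stopifnot(is(ps, "ProjectionSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (w in names(ps@counts))
    RNifti::writeNifti(RNifti::asNifti(ps@counts[[w]]),
                       file.path(dir, paste0(prefix, "_", w, ".nii.gz")))
  tal <- if (length(ps@tallies)) {
    tl <- as.data.frame(ps@tallies)
    tl$window <- rownames(ps@tallies)
    tl
  } else NULL
  side <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(geometry = geomToList(ps@geometry),
                            windows = ps@windows, tallies = tal,
                            provenance = ps@provenance),
                       side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(side)
}

#' @rdname writeProjectionSet
#' @export
readProjectionSet <- function(dir, prefix = "proj") {
  side <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  geom <- geomFromList(side$geometry)
  wt <- as.data.frame(side$windows)
  files <- list.files(dir, pattern = paste0("^", prefix, "_W[0-9]+\\.nii"),
                      full.names = TRUE)
  counts <- list()
  for (f in files) {
    w <- sub("\\.nii(\\.gz)?$", "", sub(paste0("^", prefix, "_"), "",
                                        basename(f)))
    a <- as.array(RNifti::readNifti(f))
    attributes(a) <- list(dim = dim(a))
    counts[[w]] <- a
  }
  counts <- counts[order(names(counts))]
  tal <- matrix(numeric(0), 0, 0)
  if (!is.null(side$tallies)) {
    td <- as.data.frame(side$tallies)
    rn <- td$window
    td$window <- NULL
    tal <- as.matrix(td)
    rownames(tal) <- rn
  }
  ## provenance must keep its list-of-records structure: re-read unsimplified
  raw <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                             simplifyVector = FALSE)
  prov <- raw$provenance
  if (!is.list(prov)) prov <- list()
  new("ProjectionSet", counts = counts, geometry = geom, windows = wt,
      tallies = tal, provenance = prov)
}

#' Write a volume (reconstruction or dose map) with a JSON sidecar
#'
#' @param volume 3D array.
#' @param file output NIfTI path.
#' @param voxelSize mm per voxel (scalar or length 3).
#' @param meta list of provenance entries stored in a sidecar next to
#'   `file`.
#' @return the sidecar path, invisibly.
#' @export
writeVolume <- function(volume, file, voxelSize = 1, meta = list()) {
  dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(volume,
                                     pixdim = rep_len(voxelSize, 3)), file)
  side <- sub("\\.nii(\\.gz)?$", ".json", file)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(side)
}

#' @rdname writeVolume
#' @export
readVolume <- function(file) {
  a <- as.array(RNifti::readNifti(file))
  attributes(a) <- list(dim = dim(a))
  a
}
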