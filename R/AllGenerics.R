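#' @rdname accessors
#' @export
setGeneric("activityMap", function(x) standardGeneric("activityMap"))
#' @rdname accessors
#' @export
setGeneric("attenuation", function(x) standardGeneric("attenuation"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))
#' @rdname accessors
#' @export
setGeneric("phantomGrid", function(x) standardGeneric("phantomGrid"))
#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
#' @rdname accessors
#' @export
setGeneric("windowCounts", function(x, window) standardGeneric("windowCounts"))
#' @rdname accessors
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))
#' @rdname accessors
#' @export
setGeneric("componentTallies", function(x) standardGeneric("componentTallies"))
#' @rdname accessors
#' @export
setGeneric("acqGeometry", function(x) standardGeneric("acqGeometry"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("doseMap", function(x) standardGeneric("doseMap"))
#' @rdname accessors
#' @export
setGeneric("doseSummary", function(x) standardGeneric("doseSummary"))

#' Accessors for hospect data objects
#'
#' Accessor generics for the phantom, projection, VOI and dose containers:
#' `activityMap`, `attenuation`, `regionLabels` and `regionTable` read the
#' [VoxelPhantom-class] slots; `phantomGrid` and `voxelVolume` expose the
#' sampling grid (`voxelVolume` returns ml per voxel); `windowCounts`,
#' `windowLabels`, `componentTallies`, `acqGeometry` and `provenance` read
#' [ProjectionSet-class] contents; `doseMap` and `doseSummary` read a
#' [DoseReport-class].
#'
#' @param x the object.
#' @param window a window label, e.g. `"W2"`.
#' @return The slot content; see each object's class documentation.
#' @name accessors
NULL

#' @rdname accessors
setMethod("activityMap", "VoxelPhantom", function(x) x@activity)
#' @rdname accessors
setMethod("attenuation", "VoxelPhantom", function(x) x@mu)
#' @rdname accessors
setMethod("regionLabels", "VoxelPhantom", function(x) x@labels)
#' @rdname accessors
setMethod("regionTable", "VoxelPhantom", function(x) x@regions)
#' @rdname accessors
setMethod("phantomGrid", "VoxelPhantom", function(x) x@grid)
#' @rdname accessors
setMethod("voxelVolume", "GridSpec", function(x) prod(x@voxelSize) / 1000)
#' @rdname accessors
setMethod("voxelVolume", "VoxelPhantom", function(x) voxelVolume(x@grid))

#' @rdname accessors
setMethod("windowCounts", "ProjectionSet", function(x, window) {
  if (missing(window)) return(x@counts)
  if (!window %in% names(x@counts))
    stop("no window '", window, "' in this ProjectionSet", call. = FALSE)
  x@counts[[window]]
})
#' @rdname accessors
setMethod("windowLabels", "ProjectionSet", function(x) names(x@counts))
#' @rdname accessors
setMethod("componentTallies", "ProjectionSet", function(x) x@tallies)
#' @rdname accessors
setMethod("acqGeometry", "ProjectionSet", function(x) x@geometry)
#' @rdname accessors
setMethod("provenance", "ProjectionSet", function(x) x@provenance)

#' @rdname accessors
setMethod("doseMap", "DoseReport", function(x) x@doseMap)
#' @rdname accessors
setMethod("doseSummary", "DoseReport", function(x) x@summary)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %s voxels, %s mm, origin (%s) mm\n",
              paste(object@shape, collapse = " x "),
              paste(format(object@voxelSize), collapse = " x "),
              paste(format(object@origin), collapse = ", ")))
})

setMethod("show", "VoxelPhantom", function(object) {
  cat("VoxelPhantom\n")
  show(object@grid)
  tot <- sum(object@activity) * voxelVolume(object)
  cat(sprintf("  total activity: %.2f MBq in %d regions\n", tot,
              nrow(object@regions)))
  invisible(NULL)
})

setMethod("show", "ProjectionSet", function(object) {
  g <- object@geometry
  cat(sprintf("ProjectionSet: windows [%s], %d projections of %g s over %g deg\n",
              paste(names(object@counts), collapse = ", "), g@nProjections,
              g@timePerProjection, g@angleSpan))
  for (w in names(object@counts))
    cat(sprintf("  %s: %.4g total counts\n", w, sum(object@counts[[w]])))
  invisible(NULL)
})

setMethod("show", "SpectrumComponentModel", function(object) {
  cat("SpectrumComponentModel (per-window component fractions):\n")
  print(round(object@fractions, 4))
  cat("rate scale vs W2:\n")
  print(object@rateScale)
  invisible(NULL)
})

setMethod("show", "SigmoidFit", function(object) {
  cat(sprintf("SigmoidFit: S(x) = 1/(1 + exp(-%.4g (x - %.4g))) - %.4g (RSS %.3g)\n",
              object@b, object@c, object@d, object@residualSS))
})

setMethod("show", "DoseReport", function(object) {
  cat("DoseReport\n")
  print(object@summary, digits = 4)
  invisible(NULL)
})
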