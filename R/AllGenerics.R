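#' Accessor generics
#'
#' Accessors for the package's S4 containers; use these instead of direct
#' slot access.
#'
#' @param object an S4 object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @return `pixelData()` returns the rows x cols x 3 pixel array.
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))

#' @rdname accessors
#' @return `micronsPerPixel()` returns the calibration in micrometres/pixel.
#' @export
setGeneric("micronsPerPixel", function(object) standardGeneric("micronsPerPixel"))

#' @rdname accessors
#' @return `stainType()` returns the stain/preparation identifier.
#' @export
setGeneric("stainType", function(object) standardGeneric("stainType"))

#' @rdname accessors
#' @return `sliceOrientation()` returns `"transverse"` or `"longitudinal"`.
#' @export
setGeneric("sliceOrientation", function(object) standardGeneric("sliceOrientation"))

#' @rdname accessors
#' @return `roiPolygon()` returns the n x 2 vertex matrix (0-based pixels).
#' @export
setGeneric("roiPolygon", function(object) standardGeneric("roiPolygon"))

#' @rdname accessors
#' @return `roiLabel()` returns the fascicle label.
#' @export
setGeneric("roiLabel", function(object) standardGeneric("roiLabel"))

#' @rdname accessors
#' @return `isUsable()` returns the usability flag.
#' @export
setGeneric("isUsable", function(object) standardGeneric("isUsable"))

#' @rdname accessors
#' @return `truthPerFascicle()` returns the per-fascicle ground-truth table.
#' @export
setGeneric("truthPerFascicle", function(object) standardGeneric("truthPerFascicle"))

#' @rdname accessors
#' @return `truthOverall()` returns the image-level ground-truth list.
#' @export
setGeneric("truthOverall", function(object) standardGeneric("truthOverall"))

#' @rdname accessors
#' @return `areaFractions()` returns the per-fascicle area-fraction table.
#' @export
setGeneric("areaFractions", function(object) standardGeneric("areaFractions"))

#' @rdname accessors
#' @return `pooledPctArea()` returns the section-pooled percent area.
#' @export
setGeneric("pooledPctArea", function(object) standardGeneric("pooledPctArea"))

#' @rdname accessors
#' @return `corEstimate()` returns the correlation coefficient.
#' @export
setGeneric("corEstimate", function(object) standardGeneric("corEstimate"))

#' @rdname accessors
#' @return `corCI()` returns `c(low, high)` of the 95% CI.
#' @export
setGeneric("corCI", function(object) standardGeneric("corCI"))

#' @rdname accessors
#' @return `corPValue()` returns the two-tailed p value.
#' @export
setGeneric("corPValue", function(object) standardGeneric("corPValue"))

#' @rdname accessors
#' @return `corN()` returns the number of complete pairs.
#' @export
setGeneric("corN", function(object) standardGeneric("corN"))

#' @rdname accessors
#' @export
setMethod("pixelData", "SlideImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setMethod("micronsPerPixel", "SlideImage", function(object) object@micronsPerPixel)

#' @rdname accessors
#' @export
setMethod("stainType", "SlideImage", function(object) object@stain)

#' @rdname accessors
#' @export
setMethod("sliceOrientation", "SlideImage", function(object) object@orientation)

#' @rdname accessors
#' @export
setMethod("roiPolygon", "FascicleROI", function(object) object@polygon)

#' @rdname accessors
#' @export
setMethod("roiLabel", "FascicleROI", function(object) object@label)

#' @rdname accessors
#' @export
setMethod("isUsable", "FascicleROI", function(object) object@usable)

#' @rdname accessors
#' @export
setMethod("truthPerFascicle", "RenderTruth", function(object) object@perFascicle)

#' @rdname accessors
#' @export
setMethod("truthOverall", "RenderTruth", function(object) object@overall)

#' @rdname accessors
#' @export
setMethod("areaFractions", "AreaFractionResult", function(object) object@perFascicle)

#' @rdname accessors
#' @export
setMethod("pooledPctArea", "AreaFractionResult", function(object) object@pooledPctArea)

#' @rdname accessors
#' @export
setMethod("corEstimate", "CorrelationResult", function(object) object@r)

#' @rdname accessors
#' @export
setMethod("corCI", "CorrelationResult", function(object) c(object@ciLow, object@ciHigh))

#' @rdname accessors
#' @export
setMethod("corPValue", "CorrelationResult", function(object) object@p)

#' @rdname accessors
#' @export
setMethod("corN", "CorrelationResult", function(object) object@n)

setMethod("show", "SlideImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SlideImage: %d x %d px, %.3g um/px, %s, %s\n",
              d[1], d[2], object@micronsPerPixel, object@stain,
              object@orientation))
})

setMethod("show", "FascicleROI", function(object) {
  cat(sprintf("FascicleROI '%s': %d vertices, area %.1f px^2, usable = %s\n",
              object@label, nrow(object@polygon),
              abs(shoelaceArea(object@polygon)), object@usable))
})

setMethod("show", "RenderTruth", function(object) {
  cat(sprintf("RenderTruth: %d fascicle(s)\n", nrow(object@perFascicle)))
  print(object@perFascicle)
})

setMethod("show", "AreaFractionResult", function(object) {
  cat(sprintf("AreaFractionResult: pooled %.3f%% over %d fascicle(s), %d object(s)\n",
              object@pooledPctArea, nrow(object@perFascicle),
              object@objectCount))
})

setMethod("show", "MorphometryResult", function(object) {
  cat(sprintf(paste0("MorphometryResult: %.1f fibers/mm^2 (n = %d), ",
                     "%.1f degenerating/mm^2 (n = %d), %d usable / %d ",
                     "excluded fascicle(s)\n"),
              object@fiberDensity, object@fiberCount, object@degenDensity,
              object@degenCount, object@usableFascicles,
              object@excludedFascicles))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(formatCorrelation(object), "\n")
})

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary\n")
  cat(sprintf("  patients: %d (%d m / %d f)\n", object@nTotal, object@nMale,
              object@nFemale))
  cat(sprintf("  CNS disease: %d\n", object@nCnsYes))
  cat(sprintf("  vasculitis (definite/probable): %d (%d acute or subacute)\n",
              object@nVasculitis, object@nVasculitisAcuteOrSubacute))
  cat(sprintf("  other diagnoses: %d\n", object@nOtherDx))
  cat(sprintf("  median days biosample to biopsy: %g\n",
              object@medianDeltaDays))
})
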