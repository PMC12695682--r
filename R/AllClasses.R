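#' @title Core S4 classes
#' @name nflaxon-classes
#' @description S4 containers for calibrated micrographs, fascicle regions of
#'   interest, render ground truth, quantification results and correlation
#'   results.
NULL

VALID_STAINS <- c("nf70_dab", "cd68_dab", "methylene_blue_semithin", "teased_ppd")
VALID_ORIENTATIONS <- c("transverse", "longitudinal")

#' SlideImage: a calibrated RGB brightfield micrograph
#'
#' Pixel values are stored as a height x width x 3 numeric array on the
#' 0--255 scale, together with the micron-per-pixel calibration, the section
#' orientation and the preparation/stain type.
#'
#' @slot pixels numeric array, `dim = c(rows, cols, 3)`, values in \[0, 255\].
#' @slot micronsPerPixel positive scalar, micrometres per pixel.
#' @slot orientation `"transverse"` or `"longitudinal"`.
#' @slot stain one of `"nf70_dab"`, `"cd68_dab"`,
#'   `"methylene_blue_semithin"`, `"teased_ppd"`.
#' @exportClass SlideImage
setClass("SlideImage",
  representation(
    pixels = "array",
    micronsPerPixel = "numeric",
    orientation = "character",
    stain = "character"
  )
)

setValidity("SlideImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be a rows x cols x 3 array")
  if (anyNA(object@pixels) ||
      min(object@pixels) < 0 || max(object@pixels) > 255)
    return("pixel values must lie in [0, 255]")
  if (length(object@micronsPerPixel) != 1L || object@micronsPerPixel <= 0)
    return("micronsPerPixel must be a single positive number")
  if (!object@orientation %in% VALID_ORIENTATIONS)
    return(sprintf("orientation must be one of: %s",
                   paste(VALID_ORIENTATIONS, collapse = ", ")))
  if (!object@stain %in% VALID_STAINS)
    return(sprintf("stain must be one of: %s",
                   paste(VALID_STAINS, collapse = ", ")))
  TRUE
})

#' Construct a SlideImage
#'
#' @param pixels rows x cols x 3 numeric array on the 0--255 scale.
#' @param micronsPerPixel micrometres per pixel (> 0).
#' @param orientation section orientation, `"transverse"` (default) or
#'   `"longitudinal"`.
#' @param stain preparation type; see [SlideImage-class].
#' @return A validated [SlideImage-class] object.
#' @examples
#' px <- array(255, dim = c(8, 8, 3))
#' SlideImage(px, micronsPerPixel = 0.5, stain = "nf70_dab")
#' @export
SlideImage <- function(pixels, micronsPerPixel, orientation = "transverse",
                       stain = "nf70_dab") {
  new("SlideImage", pixels = pixels, micronsPerPixel = micronsPerPixel,
      orientation = orientation, stain = stain)
}

#' FascicleROI: a polygonal nerve-fascicle region of interest
#'
#' Vertices use 0-based pixel coordinates with x rightward (column index) and
#' y downward (row index); the polygon is treated as closed (the last vertex
#' connects back to the first).
#'
#' @slot polygon numeric n x 2 matrix of (x, y) vertices.
#' @slot label fascicle label.
#' @slot usable logical; unusable fascicles are excluded from density
#'   denominators.
#' @exportClass FascicleROI
setClass("FascicleROI",
  representation(polygon = "matrix", label = "character", usable = "logical")
)

setValidity("FascicleROI", function(object) {
  p <- object@polygon
  if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 3L)
    return("polygon must be a numeric n x 2 matrix with n >= 3")
  if (anyNA(p)) return("polygon vertices must be finite")
  if (abs(shoelaceArea(p)) <= 0)
    return("polygon must enclose a positive area")
  if (!polygonIsSimple(p))
    return("polygon must be simple (non self-intersecting)")
  if (length(object@label) != 1L || length(object@usable) != 1L ||
      is.na(object@usable))
    return("label and usable must be scalars")
  TRUE
})

#' Construct a FascicleROI
#'
#' @param polygon numeric n x 2 matrix of (x, y) vertices, 0-based pixel
#'   coordinates.
#' @param label fascicle label string.
#' @param usable logical flag; defaults to `TRUE`.
#' @return A validated [FascicleROI-class] object.
#' @export
FascicleROI <- function(polygon, label = "F1", usable = TRUE) {
  polygon <- as.matrix(polygon)
  dimnames(polygon) <- NULL
  new("FascicleROI", polygon = polygon, label = label, usable = usable)
}

#' RenderTruth: construction-time ground truth of a rendered slide
#'
#' @slot perFascicle data.frame with one row per fascicle (columns depend on
#'   the preparation: painted chromogen area, fiber counts, ...).
#' @slot overall named list of image-level truth values.
#' @exportClass RenderTruth
setClass("RenderTruth",
  representation(perFascicle = "data.frame", overall = "list")
)

RenderTruth <- function(perFascicle, overall = list()) {
  new("RenderTruth", perFascicle = perFascicle, overall = overall)
}

#' AreaFractionResult: stained-area fraction of fascicular area
#'
#' @slot perFascicle data.frame with columns `label`, `fascicle_area_um2`,
#'   `stained_area_um2`, `pct_area`.
#' @slot pooledPctArea total stained area / total fascicular area x 100.
#' @slot objectCount number of retained connected components.
#' @slot threshold the threshold applied to the processed channel.
#' @exportClass AreaFractionResult
setClass("AreaFractionResult",
  representation(
    perFascicle = "data.frame",
    pooledPctArea = "numeric",
    objectCount = "integer",
    threshold = "numeric"
  )
)

setValidity("AreaFractionResult", function(object) {
  p <- object@perFascicle
  need <- c("label", "fascicle_area_um2", "stained_area_um2", "pct_area")
  if (!all(need %in% names(p))) return("perFascicle misses required columns")
  if (nrow(p) && (min(p$pct_area) < 0 || max(p$pct_area) > 100))
    return("pct_area must lie in [0, 100]")
  if (object@pooledPctArea < 0 || object@pooledPctArea > 100)
    return("pooledPctArea must lie in [0, 100]")
  TRUE
})

#' MorphometryResult: fiber and degenerating-fiber densities
#'
#' Densities are counts per usable fascicular area in fibers/mm^2.
#'
#' @slot fiberDensity healthy myelinated fibers per mm^2.
#' @slot degenDensity degenerating fibers per mm^2.
#' @slot fiberCount raw healthy fiber count over usable fascicles.
#' @slot degenCount raw degenerating count over usable fascicles.
#' @slot usableFascicles,excludedFascicles fascicle bookkeeping.
#' @slot usableAreaMm2 total usable fascicular area in mm^2.
#' @exportClass MorphometryResult
setClass("MorphometryResult",
  representation(
    fiberDensity = "numeric",
    degenDensity = "numeric",
    fiberCount = "integer",
    degenCount = "integer",
    usableFascicles = "integer",
    excludedFascicles = "integer",
    usableAreaMm2 = "numeric"
  )
)

setValidity("MorphometryResult", function(object) {
  if (object@fiberDensity < 0 || object@degenDensity < 0)
    return("densities must be non-negative")
  if (object@usableAreaMm2 <= 0) return("usable area must be positive")
  TRUE
})

#' CorrelationResult: Spearman rank correlation with CI and p
#'
#' @slot r rank correlation coefficient in \[-1, 1\].
#' @slot ciLow,ciHigh 95% confidence bounds (Fisher z; `NA` when n <= 3).
#' @slot p two-tailed p value.
#' @slot n number of complete pairs used.
#' @slot method short description of the p-value method.
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  representation(
    r = "numeric", ciLow = "numeric", ciHigh = "numeric",
    p = "numeric", n = "integer", method = "character"
  )
)

setValidity("CorrelationResult", function(object) {
  if (abs(object@r) > 1 + 1e-12) return("r must lie in [-1, 1]")
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    return("p must lie in [0, 1]")
  if (object@n < 3L) return("n must be >= 3")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      !(object@ciLow <= object@r + 1e-12 && object@r <= object@ciHigh + 1e-12))
    return("CI must bracket r")
  TRUE
})

#' CohortSummary: cohort-level counts and median biosample-to-biopsy delay
#'
#' @slot nTotal,nMale,nFemale,nCnsYes,nVasculitis,nVasculitisAcuteOrSubacute,nOtherDx counts.
#' @slot medianDeltaDays median of the signed days between biosample
#'   collection and biopsy.
#' @exportClass CohortSummary
setClass("CohortSummary",
  representation(
    nTotal = "integer", nMale = "integer", nFemale = "integer",
    nCnsYes = "integer", nVasculitis = "integer",
    nVasculitisAcuteOrSubacute = "integer", nOtherDx = "integer",
    medianDeltaDays = "numeric"
  )
)

setValidity("CohortSummary", function(object) {
  if (object@nMale + object@nFemale != object@nTotal)
    return("nMale + nFemale must equal nTotal")
  if (object@nVasculitis + object@nOtherDx != object@nTotal)
    return("nVasculitis + nOtherDx must equal nTotal")
  if (object@nVasculitisAcuteOrSubacute > object@nVasculitis)
    return("nVasculitisAcuteOrSubacute cannot exceed nVasculitis")
  TRUE
})
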