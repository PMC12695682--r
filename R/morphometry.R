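# Morphometry of methylene-blue semithin sections and teased-fiber strips.
# Myelinated fibers appear as dark rings (myelin) around a pale lumen
# (axoplasm); fibers in acute axonal degeneration appear as filled dark
# profiles. The detector thresholds the darkness channel, fills lumina,
# labels 8-connected components and classifies each candidate by its lumen
# fraction, gated by circularity and equivalent outer diameter.

#' Parameters of the semithin fiber detector
#'
#' @param lumenFractionThreshold fibers with `lumen_area / outer_area`
#'   strictly below this are classified degenerating; at or above, healthy
#'   (the conservative tie-break: ambiguous profiles count as healthy).
#' @param circularityMin minimum circularity `4 * pi * A / P^2` of the
#'   filled profile.
#' @param diameterRangeUm inclusive equivalent outer-diameter gate in um.
#' @param darknessThreshold fixed darkness threshold in \[0, 1\], or `NULL`
#'   to use Otsu on the within-ROI darkness values.
#' @param minContrast minimum within-ROI darkness range below which the
#'   section is treated as blank (no detections).
#' @return A list of class `"fiberParams"`.
#' @export
fiberParams <- function(lumenFractionThreshold = 0.10, circularityMin = 0.6,
                        diameterRangeUm = c(2, 20),
                        darknessThreshold = NULL, minContrast = 0.05) {
  stopifnot(lumenFractionThreshold > 0, lumenFractionThreshold < 1,
            circularityMin > 0, diameterRangeUm[1] < diameterRangeUm[2])
  structure(list(lumenFractionThreshold = lumenFractionThreshold,
                 circularityMin = circularityMin,
                 diameterRangeUm = diameterRangeUm,
                 darknessThreshold = darknessThreshold,
                 minContrast = minContrast),
            class = "fiberParams")
}

#' Detect myelinated and degenerating fibers in a semithin section
#'
#' Dark-ring detection on the darkness channel: threshold -> fill lumina ->
#' 8-connected components -> per-component lumen analysis. Components
#' passing the circularity and diameter gates become fiber detections;
#' a lumen fraction strictly below the threshold classifies a fiber as
#' degenerating, otherwise healthy.
#'
#' @param image a [SlideImage-class] of a transverse semithin section.
#' @param rois list of [FascicleROI-class]; detection runs over all ROIs
#'   (usability is applied later by the density functions).
#' @param params a [fiberParams()].
#' @return data.frame with one row per detection: `fascicle_label`,
#'   `centroid_x`, `centroid_y` (0-based pixels), `outer_area_um2`,
#'   `lumen_area_um2`, `lumen_fraction`, `circularity`,
#'   `equiv_diameter_um`, `classification`.
#' @examples
#' r <- renderSemithin(8, 2, seed = 3, imageSize = c(128, 128),
#'                     micronsPerPixel = 1, noiseSd = 0)
#' table(detectFibers(r$image, r$rois)$classification)
#' @export
detectFibers <- function(image, rois, params = fiberParams()) {
  stopifnot(is(image, "SlideImage"), inherits(params, "fiberParams"))
  if (!length(rois)) stop("no fascicle ROI given", call. = FALSE)
  rm <- roiMasks(image, rois, usableOnly = FALSE)
  dark <- darknessChannel(image)
  vals <- dark[rm$union]
  empty <- data.frame(fascicle_label = character(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), outer_area_um2 = numeric(0),
                      lumen_area_um2 = numeric(0), lumen_fraction = numeric(0),
                      circularity = numeric(0), equiv_diameter_um = numeric(0),
                      classification = character(0), stringsAsFactors = FALSE)
  if (diff(range(vals)) < params$minContrast) return(empty)
  thr <- if (is.null(params$darknessThreshold))
    otsuThreshold(vals) else params$darknessThreshold
  mask <- dark > thr & rm$union
  filled <- EBImage::fillHull(mask * 1L) > 0L
  lab <- label8(filled)
  n <- max(lab)
  if (n == 0L) return(empty)

  shp <- EBImage::computeFeatures.shape(lab)
  outerPx <- tabulate(lab[lab > 0L], nbins = n)
  myelinPx <- tabulate(lab[mask & lab > 0L], nbins = n)
  lumenPx <- outerPx - myelinPx
  mpp <- micronsPerPixel(image)
  circ <- 4 * pi * shp[, "s.area"] / pmax(shp[, "s.perimeter"], 1)^2
  equivDiam <- 2 * sqrt(outerPx / pi) * mpp

  # centroids (0-based x = col, y = row)
  idx <- which(lab > 0L)
  H <- nrow(lab)
  cy <- vapply(split((idx - 1L) %% H, lab[idx]), mean, numeric(1))
  cx <- vapply(split((idx - 1L) %/% H, lab[idx]), mean, numeric(1))

  keep <- circ >= params$circularityMin &
    equivDiam >= params$diameterRangeUm[1] &
    equivDiam <= params$diameterRangeUm[2]
  if (!any(keep)) return(empty)

  # assign each detection to the fascicle containing its centroid
  fascOf <- function(x, y) {
    r <- round(y) + 1L; c <- round(x) + 1L
    for (j in seq_along(rm$masks))
      if (rm$masks[[j]][r, c]) return(rm$labels[j])
    rm$labels[which.max(vapply(rm$masks, function(m)
      sum(m & lab == 0), numeric(1)))] # unreachable in practice
  }
  ks <- which(keep)
  data.frame(
    fascicle_label = vapply(ks, function(k) fascOf(cx[k], cy[k]), character(1)),
    centroid_x = cx[ks], centroid_y = cy[ks],
    outer_area_um2 = outerPx[ks] * mpp^2,
    lumen_area_um2 = lumenPx[ks] * mpp^2,
    lumen_fraction = lumenPx[ks] / outerPx[ks],
    circularity = unname(circ[ks]),
    equiv_diameter_um = equivDiam[ks],
    classification = ifelse(lumenPx[ks] / outerPx[ks] <
                              params$lumenFractionThreshold,
                            "degenerating", "healthy_myelinated"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# usable-area bookkeeping shared by the density functions
usableAreas <- function(rois, micronsPerPixel) {
  usable <- vapply(rois, isUsable, logical(1))
  areaMm2 <- vapply(rois, function(r)
    abs(shoelaceArea(roiPolygon(r))) * micronsPerPixel^2 / 1e6, numeric(1))
  if (sum(areaMm2[usable]) <= 0)
    stop("total usable fascicular area is zero", call. = FALSE)
  list(usable = usable, areaMm2 = areaMm2,
       labels = vapply(rois, roiLabel, character(1)))
}

#' Myelinated-fiber density over usable fascicles
#'
#' Healthy myelinated fibers per mm^2 of usable fascicular area; fascicles
#' flagged unusable (inaccurate automated detection) are excluded from both
#' numerator and denominator, and their count is reported.
#'
#' @param detections data.frame from [detectFibers()].
#' @param rois list of [FascicleROI-class] (areas from the polygon).
#' @param micronsPerPixel calibration used for the ROI areas.
#' @return A [MorphometryResult-class].
#' @export
fiberDensity <- function(detections, rois, micronsPerPixel) {
  ua <- usableAreas(rois, micronsPerPixel)
  usableLabels <- ua$labels[ua$usable]
  det <- detections[detections$fascicle_label %in% usableLabels, , drop = FALSE]
  areaMm2 <- sum(ua$areaMm2[ua$usable])
  nFib <- sum(det$classification == "healthy_myelinated")
  nDeg <- sum(det$classification == "degenerating")
  new("MorphometryResult",
      fiberDensity = nFib / areaMm2, degenDensity = nDeg / areaMm2,
      fiberCount = as.integer(nFib), degenCount = as.integer(nDeg),
      usableFascicles = sum(ua$usable),
      excludedFascicles = sum(!ua$usable),
      usableAreaMm2 = areaMm2)
}

#' Degenerating-fiber count and density
#'
#' Count and density (fibers/mm^2 of usable fascicular area) of detections
#' classified as degenerating. Classification is conservative: profiles at
#' the lumen-fraction threshold count as healthy.
#'
#' @inheritParams fiberDensity
#' @return List with `degen_count`, `degen_density_mm2`, `usable_area_mm2`.
#' @export
countDegenerating <- function(detections, rois, micronsPerPixel) {
  res <- fiberDensity(detections, rois, micronsPerPixel)
  list(degen_count = res@degenCount,
       degen_density_mm2 = res@degenDensity,
       usable_area_mm2 = res@usableAreaMm2)
}

#' Parameters of the teased-fiber ovoid detector
#'
#' @param presenceFraction fraction of the band/background contrast above
#'   which a column counts as fiber-occupied.
#' @param traceableMin minimum fraction of the strip width a fiber must be
#'   traceable across to be assessable.
#' @param minGapPx minimum gap run length (columns) to count as a
#'   fragmentation gap.
#' @param minGaps minimum number of gaps for an ovoid call.
#' @param minAssessable below this assessable-fiber count a warning is
#'   raised (sparse preparations give unstable fractions).
#' @return A list of class `"teasedParams"`.
#' @export
teasedParams <- function(presenceFraction = 0.4, traceableMin = 0.9,
                         minGapPx = 2L, minGaps = 2L, minAssessable = 20L) {
  structure(list(presenceFraction = presenceFraction,
                 traceableMin = traceableMin, minGapPx = minGapPx,
                 minGaps = minGaps, minAssessable = minAssessable),
            class = "teasedParams")
}

#' Ovoid fraction of a teased-fiber strip
#'
#' Fibers are traced as horizontal bands (runs of dark rows in the row-mean
#' darkness profile). A fiber is assessable when its longitudinal profile is
#' above the presence threshold across at least `traceableMin` of the strip
#' width; it has ovoids when the profile crosses below the
#' background-referenced threshold in at least `minGaps` distinct gaps.
#'
#' @param image a [SlideImage-class] of a teased-fiber strip.
#' @param params a [teasedParams()].
#' @return List with `ovoid_fraction`, `assessable_fibers`, `ovoid_fibers`.
#' @examples
#' r <- renderTeasedFibers(25, 5, seed = 4, noiseSd = 0)
#' ovoidFraction(r$image)
#' @export
ovoidFraction <- function(image, params = teasedParams()) {
  stopifnot(is(image, "SlideImage"), inherits(params, "teasedParams"))
  dark <- darknessChannel(image)
  W <- ncol(dark)
  rowProf <- rowMeans(dark)
  bgRow <- min(rowProf)
  hiRow <- max(rowProf)
  if (hiRow - bgRow < 0.02)
    stop("no assessable fibers found in the strip", call. = FALSE)
  bandRows <- rowProf > bgRow + 0.3 * (hiRow - bgRow)
  runs <- rle(bandRows)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  bands <- which(runs$values)

  bg <- min(dark)
  assessable <- 0L
  ovoid <- 0L
  for (b in bands) {
    rows <- starts[b]:ends[b]
    prof <- colMeans(dark[rows, , drop = FALSE])
    lvl <- max(prof)
    thr <- bg + params$presenceFraction * (lvl - bg)
    present <- prof > thr
    span <- range(which(present))
    coverage <- sum(present) / W
    if (coverage < params$traceableMin) next
    assessable <- assessable + 1L
    inner <- present[span[1]:span[2]]
    gapRuns <- rle(inner)
    nGaps <- sum(!gapRuns$values & gapRuns$lengths >= params$minGapPx)
    if (nGaps >= params$minGaps) ovoid <- ovoid + 1L
  }
  if (assessable == 0L)
    stop("no assessable fibers found in the strip", call. = FALSE)
  if (assessable < params$minAssessable)
    warning(sprintf("only %d assessable fibers (< %d); ovoid fraction may be unstable",
                    assessable, params$minAssessable))
  list(ovoid_fraction = ovoid / assessable,
       assessable_fibers = assessable,
       ovoid_fibers = ovoid)
}
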