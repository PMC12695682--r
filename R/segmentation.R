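# The two immunohistochemistry quantification chains.
#
# NF70 (chronic axonal loss): colour deconvolution -> DAB channel ->
# Laplacian-of-Gaussian edge enhancement -> Otsu binarisation within the
# fascicle ROI union -> 8-connected components -> size gate in um^2 ->
# stained area as percent of fascicular area.
#
# CD68 (macrophage infiltration): DAB channel -> rolling-ball background
# subtraction -> Yen threshold within the ROI union -> 3x3 median despeckle
# of the binary mask -> percent of fascicular area; section values are later
# normalised to the dataset maximum and averaged across orientations.

#' Parameters of the NF70 area-fraction chain
#'
#' @param minObjectAreaUm2,maxObjectAreaUm2 inclusive size gate for retained
#'   objects, in um^2 (defaults 20 and 30000).
#' @param logSigma Gaussian scale (pixels) of the Laplacian-of-Gaussian
#'   enhancement.
#' @param sharpenWeight weight of the subtracted LoG response.
#' @param minOD minimum optical density a pixel must reach in the enhanced
#'   DAB channel; guards the histogram threshold against splitting pure
#'   background noise on (near-)blank sections.
#' @param stainVectors 3 x 3 stain OD matrix for the deconvolution.
#' @return A list of class `"nf70Params"`.
#' @export
nf70Params <- function(minObjectAreaUm2 = 20, maxObjectAreaUm2 = 30000,
                       logSigma = 2, sharpenWeight = 0.25, minOD = 0.1,
                       stainVectors = stainVectorsHDAB()) {
  stopifnot(minObjectAreaUm2 > 0, minObjectAreaUm2 < maxObjectAreaUm2,
            logSigma > 0)
  structure(list(minObjectAreaUm2 = minObjectAreaUm2,
                 maxObjectAreaUm2 = maxObjectAreaUm2, logSigma = logSigma,
                 sharpenWeight = sharpenWeight, minOD = minOD,
                 stainVectors = stainVectors),
            class = "nf70Params")
}

#' Parameters of the CD68 area-fraction chain
#'
#' @param rollingBallRadius rolling-ball background radius in pixels.
#' @param minOD minimum optical density above the subtracted background (see
#'   [nf70Params()]).
#' @param stainVectors 3 x 3 stain OD matrix.
#' @return A list of class `"cd68Params"`.
#' @export
cd68Params <- function(rollingBallRadius = 50, minOD = 0.1,
                       stainVectors = stainVectorsHDAB()) {
  stopifnot(rollingBallRadius >= 1)
  structure(list(rollingBallRadius = rollingBallRadius, minOD = minOD,
                 stainVectors = stainVectors),
            class = "cd68Params")
}

# rasterise usable ROIs; returns list(masks = per-fascicle list,
# union = logical matrix, labels)
roiMasks <- function(image, rois, usableOnly = TRUE) {
  d <- dim(pixelData(image))
  keep <- if (usableOnly) vapply(rois, isUsable, logical(1)) else
    rep(TRUE, length(rois))
  rois <- rois[keep]
  if (!length(rois))
    stop("no usable fascicle ROI", call. = FALSE)
  masks <- lapply(rois, function(r) polygonMaskCached(d[1], d[2], roiPolygon(r)))
  union <- Reduce(`|`, masks)
  list(masks = masks, union = union,
       labels = vapply(rois, roiLabel, character(1)))
}

#' Rolling-ball background estimate of a grey-level image
#'
#' Grayscale morphological opening with a disc structuring element,
#' evaluated on a downsampled copy for large radii (the classic large-radius
#' strategy) and resized back.
#'
#' @param mat numeric matrix (e.g. a DAB optical-density channel).
#' @param radius ball radius in pixels.
#' @return Background matrix of the same size, elementwise `<= mat`.
#' @export
rollingBallBackground <- function(mat, radius = 50) {
  s <- max(1L, floor(radius / 8))
  if (s > 1L) {
    small <- EBImage::resize(EBImage::Image(mat),
                             w = max(4L, ceiling(nrow(mat) / s)),
                             h = max(4L, ceiling(ncol(mat) / s)))
    r <- max(1L, round(radius / s))
    bgs <- EBImage::opening(small, EBImage::makeBrush(2L * r + 1L, "disc"))
    bg <- EBImage::imageData(EBImage::resize(bgs, w = nrow(mat), h = ncol(mat)))
  } else {
    bg <- EBImage::imageData(
      EBImage::opening(EBImage::Image(mat),
                       EBImage::makeBrush(2L * round(radius) + 1L, "disc")))
  }
  pmin(matrix(bg, nrow(mat), ncol(mat)), mat)
}

# assemble an AreaFractionResult from a final stained mask
areaFractionFromMask <- function(stained, rm, micronsPerPixel, threshold,
                                 objectCount) {
  c2 <- micronsPerPixel^2
  per <- do.call(rbind, lapply(seq_along(rm$masks), function(j) {
    fm <- rm$masks[[j]]
    data.frame(label = rm$labels[j],
               fascicle_area_um2 = sum(fm) * c2,
               stained_area_um2 = sum(stained & fm) * c2,
               pct_area = 100 * sum(stained & fm) / sum(fm),
               stringsAsFactors = FALSE)
  }))
  new("AreaFractionResult", perFascicle = per,
      pooledPctArea = 100 * sum(per$stained_area_um2) /
        sum(per$fascicle_area_um2),
      objectCount = as.integer(objectCount),
      threshold = threshold)
}

# shared degenerate-section guard: TRUE when the within-ROI channel has no
# usable contrast (Otsu/Yen undefined)
degenerateRoi <- function(values) {
  diff(range(values, finite = TRUE)) < 1e-6
}

#' NF70 percent-of-fascicular-area (chronic axonal loss)
#'
#' Runs the neurofilament quantification chain (see the file header) and
#' reports the stained-area fraction per fascicle and pooled over the
#' section. Objects outside the inclusive \[min, max\] um^2 size gate are
#' discarded. A section with no within-ROI contrast yields 0% with a
#' warning (the histogram threshold is undefined there).
#'
#' @param image a [SlideImage-class] (NF70/DAB stained).
#' @param rois list of [FascicleROI-class]; only usable ROIs enter.
#' @param params a [nf70Params()].
#' @return An [AreaFractionResult-class].
#' @examples
#' r <- renderIhcSlide(8, "nf70_dab", seed = 2, imageSize = c(96, 96),
#'                     noiseSd = 0, illumGradient = 0)
#' pooledPctArea(nf70AreaFraction(r$image, r$rois))
#' @export
nf70AreaFraction <- function(image, rois, params = nf70Params()) {
  stopifnot(is(image, "SlideImage"), inherits(params, "nf70Params"))
  rm <- roiMasks(image, rois)
  dab <- colorDeconvolve(image, params$stainVectors)$dab
  k <- logKernel(params$logSigma)
  enhanced <- dab - params$sharpenWeight *
    EBImage::imageData(EBImage::filter2(EBImage::Image(dab), k,
                                        boundary = "replicate"))
  vals <- enhanced[rm$union]
  if (degenerateRoi(vals)) {
    warning("no within-ROI contrast; Otsu threshold undefined, reporting 0%")
    return(areaFractionFromMask(matrix(FALSE, nrow(dab), ncol(dab)), rm,
                                micronsPerPixel(image), NA_real_, 0L))
  }
  thr <- max(otsuThreshold(vals), params$minOD)
  mask <- enhanced > thr & rm$union
  lab <- label8(mask)
  nObj <- max(lab)
  if (nObj > 0L) {
    areasUm2 <- tabulate(lab[lab > 0L], nbins = nObj) *
      micronsPerPixel(image)^2
    keep <- which(areasUm2 >= params$minObjectAreaUm2 &
                    areasUm2 <= params$maxObjectAreaUm2)
    mask <- matrix(lab %in% keep, nrow(lab), ncol(lab)) & mask
    nObj <- length(keep)
  }
  areaFractionFromMask(mask, rm, micronsPerPixel(image), thr, nObj)
}

#' CD68 percent-of-fascicular-area (macrophage infiltration)
#'
#' Runs the macrophage quantification chain (see the file header): DAB
#' channel, rolling-ball background subtraction, Yen threshold within the
#' ROI union, and a single 3x3 median despeckle pass on the binary mask.
#'
#' @inheritParams nf70AreaFraction
#' @param params a [cd68Params()].
#' @return An [AreaFractionResult-class].
#' @export
cd68AreaFraction <- function(image, rois, params = cd68Params()) {
  stopifnot(is(image, "SlideImage"), inherits(params, "cd68Params"))
  rm <- roiMasks(image, rois)
  dab <- colorDeconvolve(image, params$stainVectors)$dab
  corrected <- dab - rollingBallBackground(dab, params$rollingBallRadius)
  vals <- corrected[rm$union]
  if (degenerateRoi(vals)) {
    warning("no within-ROI contrast; Yen threshold undefined, reporting 0%")
    return(areaFractionFromMask(matrix(FALSE, nrow(dab), ncol(dab)), rm,
                                micronsPerPixel(image), NA_real_, 0L))
  }
  thr <- max(yenThreshold(vals), params$minOD)
  mask <- corrected > thr & rm$union
  despeckled <- despeckle3x3(mask) & rm$union
  areaFractionFromMask(despeckled, rm, micronsPerPixel(image), thr,
                       max(label8(despeckled)))
}

#' Normalise section values to the dataset maximum
#'
#' Each value is expressed as a percentage of the dataset's maximum value
#' (%max); the maximum maps to 100. `NA` values are ignored when finding
#' the maximum and propagate through.
#'
#' @param values numeric vector of per-patient section values (>= 1 finite).
#' @return Values on the %max scale.
#' @examples
#' normalizeToDatasetMax(c(2, 4))
#' @export
normalizeToDatasetMax <- function(values) {
  if (!length(values) || all(is.na(values)))
    stop("no finite values to normalise", call. = FALSE)
  m <- max(values, na.rm = TRUE)
  if (m == 0) {
    warning("all values are zero; dataset maximum undefined, returning zeros")
    return(values)
  }
  if (m < 0) stop("values must be non-negative", call. = FALSE)
  values * 100 / m
}

#' Average transverse and longitudinal %max values
#'
#' The per-orientation %max macrophage values are averaged to a single
#' total-infiltration value; patients with only one orientation pass that
#' value through unchanged, and patients with neither get `NA`.
#'
#' @param transversePctMax,longitudinalPctMax numeric vectors (same length),
#'   `NA` for missing sections.
#' @return Numeric vector of total macrophage infiltration (%max).
#' @examples
#' combineOrientations(c(60, 80, NA), c(40, NA, NA))
#' @export
combineOrientations <- function(transversePctMax, longitudinalPctMax) {
  if (length(transversePctMax) != length(longitudinalPctMax))
    stop("orientation vectors must have equal length", call. = FALSE)
  out <- rowMeans(cbind(transversePctMax, longitudinalPctMax), na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}
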