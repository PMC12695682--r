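# Low-level geometry, thresholding and labelling helpers shared by the
# rendering and segmentation code.

#' Signed polygon area by the shoelace formula
#'
#' @param polygon n x 2 matrix of (x, y) vertices (closed implicitly).
#' @return Signed area in squared coordinate units (positive for
#'   counter-clockwise order in the x-right / y-down convention used here).
#' @examples
#' shoelaceArea(cbind(c(0, 4, 4, 0), c(0, 0, 3, 3)))
#' @export
shoelaceArea <- function(polygon) {
  x <- polygon[, 1]; y <- polygon[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# simple-polygon check: no two non-adjacent edges properly intersect
# (vectorised over all edge pairs)
polygonIsSimple <- function(polygon) {
  n <- nrow(polygon)
  if (n > 200L) return(TRUE) # O(n^2) guard; dense ROIs are generated convex
  x1 <- polygon[, 1]; y1 <- polygon[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  ij <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  adj <- ij[, 2] - ij[, 1] <= 1L | (ij[, 1] == 1L & ij[, 2] == n)
  i <- ij[!adj, 1]; j <- ij[!adj, 2]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross(x1[j], y1[j], x2[j], y2[j], x1[i], y1[i])
  d2 <- cross(x1[j], y1[j], x2[j], y2[j], x2[i], y2[i])
  d3 <- cross(x1[i], y1[i], x2[i], y2[i], x1[j], y1[j])
  d4 <- cross(x1[i], y1[i], x2[i], y2[i], x2[j], y2[j])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

# memoised polygon rasterisation: rendering and segmentation rasterise the
# same fascicle polygons many times over a pipeline run
.maskCache <- new.env(parent = emptyenv())
polygonMaskCached <- function(nrow, ncol, polygon) {
  key <- rlang::hash(list(nrow, ncol, polygon))
  hit <- .maskCache[[key]]
  if (!is.null(hit)) return(hit)
  if (length(ls(.maskCache)) > 64L)
    rm(list = ls(.maskCache), envir = .maskCache)
  m <- polygonMask(nrow, ncol, polygon)
  assign(key, m, envir = .maskCache)
  m
}

#' Rasterise a polygon into a logical pixel mask
#'
#' Even-odd scanline fill. Pixel centres sit at 0-based integer coordinates:
#' matrix element `[r, c]` has centre `(x = c - 1, y = r - 1)`.
#' Results for repeated polygons are memoised internally by the package.
#'
#' @param nrow,ncol dimensions of the target mask.
#' @param polygon n x 2 vertex matrix in 0-based (x, y) pixel coordinates.
#' @return Logical `nrow` x `ncol` matrix, `TRUE` inside the polygon.
#' @export
polygonMask <- function(nrow, ncol, polygon) {
  mask <- matrix(FALSE, nrow, ncol)
  x1 <- polygon[, 1]; y1 <- polygon[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  keep <- y1 != y2
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  for (r in seq_len(nrow)) {
    y0 <- r - 1
    crosses <- (y1 <= y0) != (y2 <= y0)
    if (!any(crosses)) next
    xc <- x1[crosses] + (y0 - y1[crosses]) *
      (x2[crosses] - x1[crosses]) / (y2[crosses] - y1[crosses])
    xc <- sort(xc)
    for (k in seq(1L, length(xc) - 1L, by = 2L)) {
      c0 <- max(1L, ceiling(xc[k]) + 1L)
      c1 <- min(ncol, floor(xc[k + 1L]) + 1L)
      if (c0 <= c1) mask[r, c0:c1] <- TRUE
    }
  }
  mask
}

# 8-connected component labelling (Rcpp two-pass union-find)
label8 <- function(mask) {
  storage.mode(mask) <- "logical"
  .label8cpp(mask)
}

#' Otsu threshold of a numeric sample
#'
#' Histogram-based Otsu threshold (maximum between-class variance) computed
#' over an arbitrary set of pixel values, e.g. the pixels inside a fascicle
#' ROI union. Ties in the criterion resolve to the lowest bin.
#'
#' @param values numeric vector of pixel values.
#' @param levels number of histogram bins.
#' @return The threshold (classify `value > threshold` as foreground), or
#'   `NA` if the sample is degenerate (single intensity).
#' @export
otsuThreshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  lo <- min(values); hi <- max(values)
  if (hi - lo < .Machine$double.eps * 100) return(NA_real_)
  h <- tabulate(pmin(levels, 1L + floor((values - lo) / (hi - lo) * levels)),
                nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  muT <- mu[levels]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  k <- which.max(sigmaB[-levels]) # first (lowest-bin) maximiser
  lo + (hi - lo) * k / levels
}

#' Yen threshold of a numeric sample
#'
#' Yen's maximum-correlation criterion, computed over an arbitrary pixel
#' sample (same interface as [otsuThreshold()]).
#'
#' @inheritParams otsuThreshold
#' @return The threshold, or `NA` for a degenerate sample.
#' @export
yenThreshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  lo <- min(values); hi <- max(values)
  if (hi - lo < .Machine$double.eps * 100) return(NA_real_)
  h <- tabulate(pmin(levels, 1L + floor((values - lo) / (hi - lo) * levels)),
                nbins = levels)
  p <- h / sum(h)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- sum(p^2) - P1sq
  crit <- -log(pmax(P1sq * P2sq, .Machine$double.xmin)) +
    2 * log(pmax(P1 * (1 - P1), .Machine$double.xmin))
  crit[!is.finite(crit)] <- -Inf
  k <- which.max(crit[-levels])
  lo + (hi - lo) * k / levels
}

# Zero-sum Laplacian-of-Gaussian kernel
logKernel <- function(sigma, size = 2L * ceiling(3 * sigma) + 1L) {
  half <- (size - 1L) / 2
  ax <- seq(-half, half)
  r2 <- outer(ax^2, ax^2, "+")
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k - mean(k)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# one pass of a 3x3 median filter on a binary mask == majority vote over
# the 9-neighbourhood (computed by convolution; removes isolated pixels)
despeckle3x3 <- function(mask) {
  counts <- EBImage::imageData(EBImage::filter2(
    EBImage::Image(mask * 1), matrix(1, 3, 3), boundary = "replicate"))
  matrix(counts > 4.5, nrow(mask), ncol(mask))
}

# darkness channel of a SlideImage: 0 (white) .. 1 (black)
darknessChannel <- function(image) {
  px <- pixelData(image)
  1 - (px[, , 1] + px[, , 2] + px[, , 3]) / (3 * 255)
}

# mask area in um^2 given calibration
pxToUm2 <- function(px, micronsPerPixel) px * micronsPerPixel^2
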