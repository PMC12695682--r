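# Colour deconvolution for brightfield immunohistochemistry. Stains act as
# optical-density (OD) absorbers: a pixel's OD vector is the concentration-
# weighted sum of per-stain unit OD vectors, so unmixing is a 3x3 matrix
# inverse applied per pixel (Ruifrok-Johnston scheme).

#' Haematoxylin / DAB optical-density stain matrix
#'
#' Rows are unit OD vectors (R, G, B) for haematoxylin counterstain, the DAB
#' chromogen and the orthogonal residual channel.
#'
#' @return 3 x 3 numeric matrix with rownames `hematoxylin`, `dab`,
#'   `residual`.
#' @examples
#' stainVectorsHDAB()
#' @export
stainVectorsHDAB <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  h <- h / sqrt(sum(h^2))
  d <- d / sqrt(sum(d^2))
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  r <- r / sqrt(sum(r^2))
  m <- rbind(hematoxylin = h, dab = d, residual = r)
  colnames(m) <- c("R", "G", "B")
  m
}

# per-channel optical density of 0..255 intensities
opticalDensity <- function(intensity) {
  -log10(pmax(intensity, 1) / 255)
}

#' Unmix an RGB micrograph into per-stain intensity channels
#'
#' Converts the image to optical densities (`-log10` of transmittance
#' relative to white, intensities floored at 1 grey level) and applies the
#' inverse of the stain matrix. Negative unmixed concentrations are clipped
#' to zero.
#'
#' @param image a [SlideImage-class].
#' @param stainVectors 3 x 3 stain OD matrix, rows = stains (must be
#'   invertible). Defaults to [stainVectorsHDAB()].
#' @return Named list of numeric matrices (one per stain, OD units, >= 0).
#' @examples
#' px <- array(255, dim = c(4, 4, 3))
#' chans <- colorDeconvolve(SlideImage(px, 0.5, stain = "nf70_dab"))
#' range(chans$dab)
#' @export
colorDeconvolve <- function(image, stainVectors = stainVectorsHDAB()) {
  stopifnot(is(image, "SlideImage"))
  if (!is.matrix(stainVectors) || any(dim(stainVectors) != c(3L, 3L)))
    stop("stainVectors must be a 3 x 3 matrix", call. = FALSE)
  det <- determinant(stainVectors, logarithm = FALSE)
  if (abs(det$modulus) < 1e-8)
    stop("stain matrix is singular and cannot be inverted", call. = FALSE)
  px <- pixelData(image)
  d <- dim(px)
  od <- opticalDensity(matrix(px, nrow = d[1] * d[2], ncol = 3L))
  conc <- od %*% solve(stainVectors)
  conc[conc < 0] <- 0
  nm <- rownames(stainVectors)
  if (is.null(nm)) nm <- paste0("stain", 1:3)
  setNames(lapply(1:3, function(k) matrix(conc[, k], d[1], d[2])), nm)
}

# compose an RGB array (0..255, unrounded) from per-stain concentration
# matrices and a stain matrix; inverse of colorDeconvolve up to clipping
composeStains <- function(concentrations, stainVectors = stainVectorsHDAB()) {
  d <- dim(concentrations[[1]])
  conc <- vapply(concentrations, as.numeric, numeric(d[1] * d[2]))
  od <- conc %*% stainVectors[names(concentrations), , drop = FALSE]
  rgb <- 255 * 10^(-od)
  array(rgb, dim = c(d[1], d[2], 3L))
}
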