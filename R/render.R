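# Synthetic stained-slide renderers. Every renderer returns the image, the
# fascicle ROI polygons and a RenderTruth whose numbers are derived from the
# actually painted pixel masks, so downstream segmentation and morphometry
# can be scored against exact construction-time truth.

# elliptical fascicle layout: k fascicles side by side
fascicleLayout <- function(imageSize, nFascicles = 1L, vertices = 72L) {
  H <- imageSize[1]; W <- imageSize[2]
  lapply(seq_len(nFascicles), function(j) {
    cellW <- W / nFascicles
    cx <- (j - 0.5) * cellW - 0.5
    cy <- (H - 1) / 2
    rx <- 0.40 * cellW
    ry <- 0.40 * H
    th <- seq(0, 2 * pi, length.out = vertices + 1L)[-(vertices + 1L)]
    poly <- cbind(cx + rx * cos(th), cy + ry * sin(th))
    list(cx = cx, cy = cy, rx = rx, ry = ry, polygon = poly)
  })
}

#' Fascicle area of the default elliptical layout
#'
#' Area (in mm^2) of the rasterised fascicle masks the renderers produce for
#' a given image size and calibration; used to translate target densities
#' into expected counts.
#'
#' @param imageSize `c(rows, cols)` in pixels.
#' @param micronsPerPixel calibration.
#' @param nFascicles number of fascicles in the layout.
#' @return Total fascicle area in mm^2.
#' @export
fascicleLayoutAreaMm2 <- function(imageSize, micronsPerPixel,
                                  nFascicles = 1L) {
  lay <- fascicleLayout(imageSize, nFascicles)
  px <- sum(vapply(lay, function(f)
    sum(polygonMaskCached(imageSize[1], imageSize[2], f$polygon)), numeric(1)))
  px * micronsPerPixel^2 / 1e6
}

# multiplicative illumination gradient + additive Gaussian sensor noise,
# then quantisation to integer 0..255
finalizeRgb <- function(rgb, noiseSd = 0, illumGradient = 0) {
  d <- dim(rgb)
  if (illumGradient != 0) {
    fac <- 1 + illumGradient * ((seq_len(d[2]) - 1) / max(1, d[2] - 1) - 0.5)
    for (k in 1:3) rgb[, , k] <- sweep(rgb[, , k], 2, fac, `*`)
  }
  if (noiseSd > 0) rgb <- rgb + array(rnorm(length(rgb), 0, noiseSd), d)
  array(round(clamp(rgb, 0, 255)), d)
}

# grow a blob of exactly `need` pixels around a centre, using the nearest
# currently unpainted fascicle pixels (deterministic tie-break by index)
growBlob <- function(need, cx, cy, fx, fy, unpainted) {
  cand <- which(unpainted)
  if (length(cand) < need) return(NULL)
  d2 <- (fx[cand] - cx)^2 + (fy[cand] - cy)^2
  # restrict the sort to a generous radius around the centre, widening if
  # the neighbourhood is already crowded
  r2 <- (sqrt(need / pi) + 4)^2
  repeat {
    near <- d2 <= r2
    if (sum(near) >= need) break
    r2 <- r2 * 2
  }
  cand <- cand[near]; d2 <- d2[near]
  cand[order(d2, cand)[seq_len(need)]]
}

#' Render a DAB immunohistochemistry slide with known stained area
#'
#' Paints brown (DAB-like) chromogen blobs over a pale haematoxylin
#' counterstain inside elliptical fascicles, using the same optical-density
#' stain model that [colorDeconvolve()] inverts. Blobs are painted with
#' exact pixel areas, so the achieved stained area equals the request and
#' `RenderTruth` records it from the painted mask.
#'
#' @param targetPctArea requested stained percent of fascicular area per
#'   fascicle, in \[0, 80\]. Ignored when `objectAreasUm2` is given.
#' @param stain `"nf70_dab"` or `"cd68_dab"`.
#' @param seed optional integer seed.
#' @param imageSize `c(rows, cols)` in pixels.
#' @param micronsPerPixel calibration (default 0.5, a 40x-scan analogue).
#' @param nFascicles number of elliptical fascicles.
#' @param objectAreaUm2 min/max of the log-uniform blob-size distribution in
#'   um^2 (defaults 30--300 for NF70, 100--600 for CD68).
#' @param objectAreasUm2 optional vector of explicit per-object areas (um^2);
#'   objects are placed round-robin across fascicles.
#' @param orientation section orientation recorded in the image.
#' @param counterstainOD,chromogenOD optical-density amplitudes of the
#'   counterstain and chromogen.
#' @param noiseSd Gaussian sensor-noise SD in intensity units (0--255 scale).
#' @param illumGradient relative amplitude of a mild left-right illumination
#'   gradient; set `noiseSd = 0, illumGradient = 0` for noiseless renders.
#' @return List with `image` ([SlideImage-class]), `rois` (list of
#'   [FascicleROI-class]) and `truth` ([RenderTruth-class]; per-fascicle
#'   `stained_area_um2`, `fascicle_area_um2`, `pct_area`, `object_count`).
#' @examples
#' r <- renderIhcSlide(5, "nf70_dab", seed = 1, imageSize = c(96, 96),
#'                     noiseSd = 0, illumGradient = 0)
#' truthPerFascicle(r$truth)
#' @export
renderIhcSlide <- function(targetPctArea = NULL, stain = "nf70_dab",
                           seed = NULL, imageSize = c(256L, 256L),
                           micronsPerPixel = 0.5, nFascicles = 2L,
                           objectAreaUm2 = NULL, objectAreasUm2 = NULL,
                           orientation = "transverse",
                           counterstainOD = 0.30, chromogenOD = 0.85,
                           noiseSd = 3, illumGradient = 0.04) {
  if (!is.null(seed)) set.seed(seed)
  stain <- match.arg(stain, c("nf70_dab", "cd68_dab"))
  if (is.null(objectAreaUm2))
    objectAreaUm2 <- if (stain == "nf70_dab") c(30, 300) else c(100, 600)
  if (is.null(targetPctArea) && is.null(objectAreasUm2))
    stop("either targetPctArea or objectAreasUm2 must be given", call. = FALSE)
  if (!is.null(targetPctArea) &&
      (targetPctArea < 0 || targetPctArea > 80))
    stop("targetPctArea must lie in [0, 80]", call. = FALSE)

  H <- imageSize[1]; W <- imageSize[2]
  c2 <- micronsPerPixel^2
  lay <- fascicleLayout(imageSize, nFascicles)
  painted <- matrix(FALSE, H, W)
  perFasc <- vector("list", nFascicles)
  fascMasks <- vector("list", nFascicles)

  explicit <- !is.null(objectAreasUm2)
  if (explicit && length(objectAreasUm2))
    objSplit <- split(objectAreasUm2,
                      rep(seq_len(nFascicles),
                          length.out = length(objectAreasUm2)))

  for (j in seq_len(nFascicles)) {
    f <- lay[[j]]
    fm <- polygonMaskCached(H, W, f$polygon)
    fascMasks[[j]] <- fm
    idx <- which(fm)
    fy <- (idx - 1L) %% H        # 0-based row
    fx <- (idx - 1L) %/% H       # 0-based col
    unp <- rep(TRUE, length(idx))
    nPx <- length(idx)

    if (explicit) {
      areas <- if (j <= length(objSplit)) objSplit[[j]] else numeric(0)
      areasPx <- round(areas / c2)
      if (sum(areasPx) > 0.9 * nPx)
        stop("infeasible packing: requested object area exceeds fascicle area",
             call. = FALSE)
      centres <- list()
      for (a in areasPx) {
        ok <- FALSE
        for (try in 1:200) {
          ci <- sample.int(nPx, 1L)
          rNeed <- sqrt(a / pi) + 2
          far <- all(vapply(centres, function(ct)
            sqrt((fx[ci] - ct[1])^2 + (fy[ci] - ct[2])^2) >
              rNeed + ct[3], logical(1)))
          # centre must leave room inside the fascicle
          inRoom <- (fx[ci] - f$cx)^2 / max(1e-9, (f$rx - rNeed))^2 +
            (fy[ci] - f$cy)^2 / max(1e-9, (f$ry - rNeed))^2 <= 1 &&
            f$rx > rNeed && f$ry > rNeed
          if (far && inRoom && unp[ci]) { ok <- TRUE; break }
        }
        if (!ok) ci <- which(unp)[1L] # fall back: any free pixel
        sel <- growBlob(a, fx[ci], fy[ci], fx, fy, unp)
        if (is.null(sel))
          stop("infeasible packing: requested object area exceeds fascicle area",
               call. = FALSE)
        unp[sel] <- FALSE
        centres[[length(centres) + 1L]] <- c(fx[ci], fy[ci], sqrt(a / pi))
      }
    } else {
      target <- round(targetPctArea / 100 * nPx)
      if (target > 0.9 * nPx)
        stop("infeasible packing: requested area exceeds fascicle area",
             call. = FALSE)
      minPx <- max(1L, round(objectAreaUm2[1] / c2))
      maxPx <- max(minPx, round(objectAreaUm2[2] / c2))
      paintedPx <- 0L
      lastCentre <- NULL
      while (paintedPx < target) {
        remaining <- target - paintedPx
        if (remaining < minPx && !is.null(lastCentre)) {
          # merge the remainder into the previous blob so no painted object
          # falls below the detection size floor
          sel <- growBlob(remaining, lastCentre[1], lastCentre[2], fx, fy, unp)
        } else {
          a <- round(exp(runif(1, log(minPx), log(maxPx))))
          need <- min(a, remaining)
          if (remaining - need < minPx) need <- remaining
          free <- which(unp)
          ci <- free[sample.int(length(free), 1L)]
          lastCentre <- c(fx[ci], fy[ci])
          sel <- growBlob(need, fx[ci], fy[ci], fx, fy, unp)
        }
        if (is.null(sel))
          stop("infeasible packing: requested area exceeds fascicle area",
               call. = FALSE)
        unp[sel] <- FALSE
        paintedPx <- paintedPx + length(sel)
      }
    }

    blobMask <- matrix(FALSE, H, W)
    blobMask[idx[!unp]] <- TRUE
    painted <- painted | blobMask
    perFasc[[j]] <- data.frame(
      label = sprintf("F%d", j),
      fascicle_area_um2 = nPx * c2,
      stained_area_um2 = sum(!unp) * c2,
      pct_area = 100 * sum(!unp) / nPx,
      object_count = max(label8(blobMask)),
      stringsAsFactors = FALSE
    )
  }

  concH <- matrix(counterstainOD, H, W)
  concD <- matrix(0, H, W)
  concD[painted] <- chromogenOD
  rgb <- composeStains(list(hematoxylin = concH, dab = concD))
  rgb <- finalizeRgb(rgb, noiseSd, illumGradient)

  rois <- lapply(seq_len(nFascicles), function(j)
    FascicleROI(lay[[j]]$polygon, sprintf("F%d", j)))
  perFasc <- do.call(rbind, perFasc)
  list(
    image = SlideImage(rgb, micronsPerPixel, orientation, stain),
    rois = rois,
    truth = RenderTruth(perFasc, list(
      pct_area = 100 * sum(perFasc$stained_area_um2) /
        sum(perFasc$fascicle_area_um2)))
  )
}

#' Render a methylene-blue semithin section with known fiber counts
#'
#' Places exactly `fiberCount` healthy myelinated fibers (dark myelin
#' annulus around a pale axoplasm lumen) and `degeneratingCount` fibers in
#' acute axonal degeneration (filled profiles with grey-violet myelin
#' collapse) inside an elliptical fascicle, without overlap.
#'
#' @param fiberCount number of healthy myelinated fibers.
#' @param degeneratingCount number of degenerating (filled) profiles.
#' @param seed optional integer seed.
#' @param imageSize `c(rows, cols)` in pixels.
#' @param micronsPerPixel calibration.
#' @param outerDiameterUmRange sampled outer fiber diameter range (um).
#' @param gRatioRange lumen/outer radius ratio range for healthy fibers.
#' @param noiseSd Gaussian sensor-noise SD (0 for noiseless).
#' @param maxTries placement attempts per fiber before failing.
#' @return List with `image`, `rois`, `truth` (per-fascicle `fiber_count`,
#'   `degenerating_count`, `fascicle_area_um2`).
#' @examples
#' r <- renderSemithin(10, 2, seed = 1, imageSize = c(128, 128),
#'                     micronsPerPixel = 1, noiseSd = 0)
#' truthPerFascicle(r$truth)
#' @export
renderSemithin <- function(fiberCount, degeneratingCount = 0L, seed = NULL,
                           imageSize = c(240L, 320L), micronsPerPixel = 0.5,
                           outerDiameterUmRange = c(5, 12),
                           gRatioRange = c(0.5, 0.7),
                           noiseSd = 3, maxTries = 400L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(fiberCount >= 0, degeneratingCount >= 0)
  H <- imageSize[1]; W <- imageSize[2]
  lay <- fascicleLayout(imageSize, 1L)[[1]]
  fm <- polygonMaskCached(H, W, lay$polygon)

  n <- fiberCount + degeneratingCount
  type <- rep(c("healthy", "degen"), c(fiberCount, degeneratingCount))
  roPx <- runif(n, outerDiameterUmRange[1], outerDiameterUmRange[2]) /
    2 / micronsPerPixel
  # a ring thinner than sqrt(2) px can break at unlucky grid alignments and
  # a lumen needs >= 1 px; keep outer radius >= 3 px at any calibration
  roPx <- pmax(roPx, 3)
  ord <- order(-roPx)                  # large first eases packing
  roPx <- roPx[ord]; type <- type[ord]

  cx <- numeric(0); cy <- numeric(0); cr <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(maxTries)) {
      th <- runif(1, 0, 2 * pi)
      u <- sqrt(runif(1))
      # margin keeps fibers clear of the rasterised ROI boundary so rings
      # are never clipped open
      px <- lay$cx + u * (lay$rx - roPx[i] - 3) * cos(th)
      py <- lay$cy + u * (lay$ry - roPx[i] - 3) * sin(th)
      if (length(cx) == 0 ||
          all((px - cx)^2 + (py - cy)^2 >= (roPx[i] + cr + 2.2)^2)) {
        cx <- c(cx, px); cy <- c(cy, py); cr <- c(cr, roPx[i])
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("fiber packing failed after bounded retries; ",
           "reduce the fiber density or enlarge the fascicle", call. = FALSE)
  }

  bg <- c(235, 235, 245); lumen <- c(215, 215, 235)
  myelin <- c(45, 45, 130); degen <- c(110, 85, 130)
  rgb <- array(0, dim = c(H, W, 3L))
  for (k in 1:3) rgb[, , k] <- bg[k]
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  for (i in seq_len(n)) {
    ro <- cr[i]
    win <- which(abs(xs - cx[i]) <= ro + 1 & abs(ys - cy[i]) <= ro + 1)
    d2 <- (xs[win] - cx[i])^2 + (ys[win] - cy[i])^2
    if (type[i] == "degen") {
      sel <- win[d2 <= ro^2]
      for (k in 1:3) rgb[, , k][sel] <- degen[k]
    } else {
      ri <- max(1.3, min(ro * runif(1, gRatioRange[1], gRatioRange[2]),
                         ro - 1.6))
      ring <- win[d2 <= ro^2 & d2 > ri^2]
      core <- win[d2 <= ri^2]
      for (k in 1:3) rgb[, , k][ring] <- myelin[k]
      for (k in 1:3) rgb[, , k][core] <- lumen[k]
    }
  }
  rgb <- finalizeRgb(rgb, noiseSd, 0)

  truth <- data.frame(
    label = "F1",
    fascicle_area_um2 = sum(fm) * micronsPerPixel^2,
    fiber_count = fiberCount,
    degenerating_count = degeneratingCount,
    stringsAsFactors = FALSE
  )
  list(
    image = SlideImage(rgb, micronsPerPixel, "transverse",
                       "methylene_blue_semithin"),
    rois = list(FascicleROI(lay$polygon, "F1")),
    truth = RenderTruth(truth, list(
      fiber_density_mm2 = fiberCount /
        (truth$fascicle_area_um2 / 1e6),
      degen_density_mm2 = degeneratingCount /
        (truth$fascicle_area_um2 / 1e6)))
  )
}

#' Render a teased-fiber strip with known ovoid fraction
#'
#' Parallel horizontal fibers on a pale background; fibers undergoing
#' Wallerian degeneration are drawn as chains of myelin ovoid fragments
#' separated by short gaps (at least two gaps per ovoid fiber, total gap
#' length below 10% of the strip width so the fiber stays assessable).
#'
#' @param totalFibers number of fibers in the strip (>= 1).
#' @param ovoidFibers number of fibers with ovoid formations
#'   (0 <= ovoidFibers <= totalFibers).
#' @param seed optional integer seed.
#' @param widthPx strip width in pixels.
#' @param laneHeightPx vertical spacing per fiber lane.
#' @param fiberThicknessPx fiber thickness in pixels.
#' @param micronsPerPixel calibration.
#' @param noiseSd Gaussian sensor-noise SD.
#' @return List with `image` and `truth` (`total_fiber_count`,
#'   `ovoid_fiber_count`, `ovoid_fraction`).
#' @examples
#' r <- renderTeasedFibers(10, 2, seed = 1, noiseSd = 0)
#' truthOverall(r$truth)
#' @export
renderTeasedFibers <- function(totalFibers, ovoidFibers, seed = NULL,
                               widthPx = 400L, laneHeightPx = 12L,
                               fiberThicknessPx = 4L, micronsPerPixel = 0.5,
                               noiseSd = 3) {
  if (!is.null(seed)) set.seed(seed)
  if (totalFibers < 1L) stop("totalFibers must be >= 1", call. = FALSE)
  if (ovoidFibers < 0L || ovoidFibers > totalFibers)
    stop("ovoidFibers must lie in [0, totalFibers]", call. = FALSE)
  W <- widthPx
  H <- laneHeightPx * (totalFibers + 1L)
  margin <- 6L
  bg <- c(232, 228, 236); fib <- c(60, 52, 46)
  rgb <- array(0, dim = c(H, W, 3L))
  for (k in 1:3) rgb[, , k] <- bg[k]

  ovoidLane <- sort(sample.int(totalFibers, ovoidFibers))
  for (i in seq_len(totalFibers)) {
    cy <- laneHeightPx * i
    rows <- (cy - floor(fiberThicknessPx / 2)):(cy + ceiling(fiberThicknessPx / 2) - 1L)
    cols <- (margin + 1L):(W - margin)
    keep <- rep(TRUE, length(cols))
    if (i %in% ovoidLane) {
      nGaps <- sample(2:3, 1L)
      span <- range(cols)
      centres <- numeric(0)
      for (g in seq_len(nGaps)) {
        for (t in 1:50) {
          gc <- round(runif(1, span[1] + 0.15 * W, span[2] - 0.15 * W))
          if (all(abs(gc - centres) > 30)) { centres <- c(centres, gc); break }
        }
      }
      gw <- sample(4:6, length(centres), replace = TRUE)
      for (g in seq_along(centres)) {
        gapCols <- (centres[g] - floor(gw[g] / 2)):(centres[g] + ceiling(gw[g] / 2) - 1L)
        keep[cols %in% gapCols] <- FALSE
      }
    }
    for (k in 1:3) rgb[rows, cols[keep], k] <- fib[k]
  }
  rgb <- finalizeRgb(rgb, noiseSd, 0)

  list(
    image = SlideImage(rgb, micronsPerPixel, "longitudinal", "teased_ppd"),
    truth = RenderTruth(
      data.frame(label = "strip", total_fiber_count = totalFibers,
                 ovoid_fiber_count = ovoidFibers,
                 stringsAsFactors = FALSE),
      list(total_fiber_count = totalFibers,
           ovoid_fiber_count = ovoidFibers,
           ovoid_fraction = ovoidFibers / totalFibers))
  )
}

#' Write and read a SlideImage as TIFF with a JSON metadata sidecar
#'
#' The RGB raster is written as an 8-bit TIFF; calibration, stain and
#' orientation go into `<path>.json`.
#'
#' @param image a [SlideImage-class].
#' @param path TIFF output path.
#' @return `writeSlideImage()` returns the path invisibly;
#'   `readSlideImage()` returns the [SlideImage-class].
#' @export
writeSlideImage <- function(image, path) {
  stopifnot(is(image, "SlideImage"))
  tiff::writeTIFF(pixelData(image) / 255, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(microns_per_pixel = micronsPerPixel(image),
         orientation = sliceOrientation(image), stain = stainType(image)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSlideImage
#' @export
readSlideImage <- function(path) {
  px <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  SlideImage(round(px * 255), meta$microns_per_pixel, meta$orientation,
             meta$stain)
}

#' Write and read fascicle ROIs as GeoJSON
#'
#' Polygons in 0-based pixel coordinates, with `label` and `usable` feature
#' properties.
#'
#' @param rois list of [FascicleROI-class].
#' @param path GeoJSON file path.
#' @return `writeRoiGeoJSON()` returns the path invisibly;
#'   `readRoiGeoJSON()` the ROI list.
#' @export
writeRoiGeoJSON <- function(rois, path) {
  feats <- lapply(rois, function(r) {
    p <- roiPolygon(r)
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(label = roiLabel(r), usable = isUsable(r)),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRoiGeoJSON
#' @export
readRoiGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    p <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    p <- p[-nrow(p), , drop = FALSE] # drop closing vertex
    FascicleROI(p, f$properties$label, isTRUE(f$properties$usable))
  })
}
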