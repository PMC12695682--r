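test_that("IHC renders hit the requested stained area exactly", {
  r <- renderIhcSlide(0, "nf70_dab", seed = 1, imageSize = c(96, 96),
                      noiseSd = 0, illumGradient = 0)
  tr <- truthPerFascicle(r$truth)
  expect_equal(sum(tr$stained_area_um2), 0)

  r <- renderIhcSlide(10, "nf70_dab", seed = 1, imageSize = c(160, 160),
                      nFascicles = 1L)
  tr <- truthPerFascicle(r$truth)
  expect_gte(tr$stained_area_um2, 0.095 * tr$fascicle_area_um2)
  expect_lte(tr$stained_area_um2, 0.105 * tr$fascicle_area_um2)
})

test_that("an explicit object records truth area = painted pixels x calibration^2", {
  r <- renderIhcSlide(objectAreasUm2 = 80, stain = "nf70_dab", seed = 2,
                      imageSize = c(96, 96), micronsPerPixel = 0.5,
                      nFascicles = 1L, noiseSd = 0, illumGradient = 0)
  dab <- colorDeconvolve(r$image)$dab
  paintedPx <- sum(dab > 0.4)
  expect_equal(truthPerFascicle(r$truth)$stained_area_um2,
               paintedPx * 0.5^2)
  expect_equal(truthPerFascicle(r$truth)$stained_area_um2, 80)
})

test_that("renders are deterministic under a fixed seed", {
  a <- renderIhcSlide(7, "cd68_dab", seed = 9, imageSize = c(96, 96))
  b <- renderIhcSlide(7, "cd68_dab", seed = 9, imageSize = c(96, 96))
  expect_identical(pixelData(a$image), pixelData(b$image))
  s1 <- renderSemithin(12, 3, seed = 4, imageSize = c(128, 128),
                       micronsPerPixel = 1)
  s2 <- renderSemithin(12, 3, seed = 4, imageSize = c(128, 128),
                       micronsPerPixel = 1)
  expect_identical(pixelData(s1$image), pixelData(s2$image))
})

test_that("requests beyond the fascicle area fail as infeasible packing", {
  expect_error(renderIhcSlide(objectAreasUm2 = 1e6, stain = "nf70_dab",
                              imageSize = c(64, 64), micronsPerPixel = 0.5,
                              nFascicles = 1L),
               "infeasible")
  expect_error(renderSemithin(5000, 0, seed = 1, imageSize = c(96, 96),
                              micronsPerPixel = 1),
               "packing")
})

test_that("semithin and teased truths are exact by construction", {
  s <- renderSemithin(50, 7, seed = 6, imageSize = c(320, 320),
                      micronsPerPixel = 0.5)
  tr <- truthPerFascicle(s$truth)
  expect_equal(tr$fiber_count, 50L)
  expect_equal(tr$degenerating_count, 7L)
  # density arithmetic on the truth
  expect_equal(truthOverall(s$truth)$fiber_density_mm2,
               50 / (tr$fascicle_area_um2 / 1e6))

  t1 <- renderTeasedFibers(25, 5, seed = 1)
  expect_equal(truthOverall(t1$truth)$ovoid_fraction, 0.2)
  t2 <- renderTeasedFibers(20, 0, seed = 1)
  expect_equal(truthOverall(t2$truth)$ovoid_fraction, 0)
  t3 <- renderTeasedFibers(53, 53, seed = 1)
  expect_equal(truthOverall(t3$truth)$ovoid_fraction, 1)
  expect_error(renderTeasedFibers(10, 11), "ovoidFibers")
})

test_that("the stain model unmixes its own chromogen cleanly", {
  sv <- stainVectorsHDAB()
  px <- nflaxon:::composeStains(
    list(hematoxylin = matrix(0, 2, 2), dab = matrix(0.9, 2, 2)), sv)
  img <- SlideImage(round(px), 0.5, stain = "nf70_dab")
  ch <- colorDeconvolve(img, sv)
  tot <- ch$hematoxylin + ch$dab + ch$residual
  expect_true(all(ch$dab / tot >= 0.95))
})

test_that("slide images and ROIs round trip through TIFF and GeoJSON", {
  r <- renderIhcSlide(6, "nf70_dab", seed = 12, imageSize = c(64, 64))
  f <- tempfile(fileext = ".tif")
  writeSlideImage(r$image, f)
  back <- readSlideImage(f)
  expect_equal(pixelData(back), pixelData(r$image))
  expect_equal(micronsPerPixel(back), micronsPerPixel(r$image))
  expect_equal(stainType(back), "nf70_dab")

  g <- tempfile(fileext = ".geojson")
  writeRoiGeoJSON(r$rois, g)
  rois <- readRoiGeoJSON(g)
  expect_equal(length(rois), length(r$rois))
  expect_equal(roiPolygon(rois[[1]]), roiPolygon(r$rois[[1]]))
  expect_identical(roiLabel(rois[[2]]), roiLabel(r$rois[[2]]))
})

test_that("polygon utilities: shoelace area, rasterisation, validity", {
  sq <- cbind(c(0, 4, 4, 0), c(0, 0, 3, 3))
  expect_equal(abs(shoelaceArea(sq)), 12)
  m <- polygonMask(10, 10, sq)
  # rows y = 0,1,2 (top edge half-open), columns x = 0..4
  expect_equal(sum(m), 15)
  # self-intersecting polygons are rejected
  bow <- cbind(c(0, 4, 0, 4), c(0, 3, 3, 0))
  expect_false(nflaxon:::polygonIsSimple(bow))
  pent <- cbind(c(0, 6, 6, 1, 0), c(0, 0, 4, -2, 4)) # area 6, self-crossing
  expect_error(FascicleROI(pent), "simple")
  expect_error(FascicleROI(cbind(c(0, 1, 2), c(0, 0, 0))), "area")
})

test_that("8-connected labelling matches a flood-fill oracle", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(max(nflaxon:::label8(m)), 1L)

  # independent oracle: BFS flood fill over the 8-neighbourhood
  floodCount <- function(mask) {
    seen <- matrix(FALSE, nrow(mask), ncol(mask))
    count <- 0L
    for (s in which(mask & !seen)) {
      if (seen[s]) next
      count <- count + 1L
      queue <- s
      seen[s] <- TRUE
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        r <- (cur - 1L) %% nrow(mask) + 1L
        c <- (cur - 1L) %/% nrow(mask) + 1L
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
              mask[rr, cc] && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            queue <- c(queue, (cc - 1L) * nrow(mask) + rr)
          }
        }
      }
    }
    count
  }
  set.seed(3)
  for (i in 1:6) {
    mm <- matrix(runif(400) < 0.25, 20, 20)
    expect_equal(max(nflaxon:::label8(mm)), floodCount(mm))
  }
})
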