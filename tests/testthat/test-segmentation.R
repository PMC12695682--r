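test_that("colour deconvolution satisfies its algebraic contracts", {
  white <- SlideImage(array(255, dim = c(3, 3, 3)), 0.5, stain = "nf70_dab")
  ch <- colorDeconvolve(white)
  expect_true(all(abs(ch$hematoxylin) < 1e-12))
  expect_true(all(abs(ch$dab) < 1e-12))

  # identity stain matrix returns the raw per-channel optical densities
  px <- array(0, dim = c(2, 2, 3))
  px[, , 1] <- 100; px[, , 2] <- 150; px[, , 3] <- 220
  img <- SlideImage(px, 0.5, stain = "nf70_dab")
  ch <- colorDeconvolve(img, diag(3))
  expect_equal(ch[[1]][1, 1], -log10(100 / 255))
  expect_equal(ch[[2]][1, 1], -log10(150 / 255))
  expect_equal(ch[[3]][1, 1], -log10(220 / 255))

  expect_error(colorDeconvolve(img, matrix(1, 3, 3)), "singular")
})

test_that("blank sections yield 0% with a degenerate-threshold warning", {
  px <- nflaxon:::composeStains(list(hematoxylin = matrix(0.3, 64, 64),
                                     dab = matrix(0, 64, 64)))
  img <- SlideImage(round(px), 0.5, stain = "nf70_dab")
  roi <- rectRoi(5, 5, 58, 58)
  expect_warning(res <- nf70AreaFraction(img, list(roi)), "undefined")
  expect_equal(pooledPctArea(res), 0)
  img2 <- SlideImage(round(px), 0.5, stain = "cd68_dab")
  expect_warning(res2 <- cd68AreaFraction(img2, list(roi)), "undefined")
  expect_equal(pooledPctArea(res2), 0)
})

test_that("NF70 area fraction recovers render truth and respects the size gate", {
  r <- renderIhcSlide(12, "nf70_dab", seed = 31, imageSize = c(160, 160),
                      nFascicles = 1L, noiseSd = 0, illumGradient = 0)
  res <- nf70AreaFraction(r$image, r$rois)
  expect_equal(pooledPctArea(res), truthOverall(r$truth)$pct_area,
               tolerance = 0.05)

  # a single object below the 20 um^2 floor contributes nothing
  r <- renderIhcSlide(objectAreasUm2 = 10, stain = "nf70_dab", seed = 32,
                      imageSize = c(96, 96), micronsPerPixel = 0.5,
                      nFascicles = 1L, noiseSd = 0, illumGradient = 0)
  expect_equal(pooledPctArea(nf70AreaFraction(r$image, r$rois)), 0)
})

test_that("adding a gated DAB object never decreases the NF70 area fraction", {
  base <- renderIhcSlide(objectAreasUm2 = 150, stain = "nf70_dab", seed = 44,
                         imageSize = c(128, 128), micronsPerPixel = 0.5,
                         nFascicles = 1L, noiseSd = 0, illumGradient = 0)
  more <- renderIhcSlide(objectAreasUm2 = c(150, 80), stain = "nf70_dab",
                         seed = 44, imageSize = c(128, 128),
                         micronsPerPixel = 0.5, nFascicles = 1L,
                         noiseSd = 0, illumGradient = 0)
  expect_gte(pooledPctArea(nf70AreaFraction(more$image, more$rois)),
             pooledPctArea(nf70AreaFraction(base$image, base$rois)))
})

test_that("area fraction is invariant to ROI vertex order and 90-degree rotation", {
  r <- renderIhcSlide(8, "nf70_dab", seed = 51, imageSize = c(128, 128),
                      nFascicles = 1L, noiseSd = 0, illumGradient = 0)
  ref <- pooledPctArea(nf70AreaFraction(r$image, r$rois))

  rev1 <- FascicleROI(roiPolygon(r$rois[[1]])[rev(seq_len(72)), ],
                      label = "F1")
  expect_equal(pooledPctArea(nf70AreaFraction(r$image, list(rev1))), ref)

  # rotate image 90 degrees clockwise and transform the polygon with it
  px <- pixelData(r$image)
  H <- dim(px)[1]
  rot <- array(0, dim = c(dim(px)[2], H, 3))
  for (k in 1:3) rot[, , k] <- t(px[H:1, , k])
  poly <- roiPolygon(r$rois[[1]])
  polyRot <- cbind(H - 1 - poly[, 2], poly[, 1])
  imgRot <- SlideImage(rot, micronsPerPixel(r$image), stain = "nf70_dab")
  got <- pooledPctArea(nf70AreaFraction(imgRot, list(FascicleROI(polyRot))))
  # +/- 1 boundary pixel tolerance on the fascicle mask
  expect_equal(got, ref, tolerance = 0.02)
})

test_that("CD68 area fraction recovers render truth after despeckling", {
  r <- renderIhcSlide(5, "cd68_dab", seed = 61, imageSize = c(192, 192),
                      nFascicles = 1L, noiseSd = 0, illumGradient = 0)
  res <- cd68AreaFraction(r$image, r$rois)
  expect_equal(pooledPctArea(res), truthOverall(r$truth)$pct_area,
               tolerance = 0.05)
  expect_true(all(nflaxon:::rollingBallBackground(
    colorDeconvolve(r$image)$dab, 50) <= colorDeconvolve(r$image)$dab + 1e-12))
})

test_that("despeckling removes isolated pixels entirely", {
  # a mask of scattered single pixels survives thresholding but not the
  # 3x3 median
  m <- matrix(FALSE, 40, 40)
  m[cbind(seq(4, 36, by = 6), seq(4, 36, by = 6))] <- TRUE
  expect_equal(sum(nflaxon:::despeckle3x3(m)), 0)
})

test_that("Otsu and Yen thresholds match independently computed references", {
  # reference values computed once with scikit-image's threshold_otsu /
  # threshold_yen (nbins = 256) on this exact sample and frozen here
  set.seed(9)
  vals <- c(rnorm(4000, 0.2, 0.03), rnorm(500, 0.7, 0.05))
  vals <- pmin(pmax(vals, 0), 1)
  expect_equal(otsuThreshold(vals, levels = 256L), 0.30126580, tolerance = 0.01)
  expect_equal(yenThreshold(vals, levels = 256L), 0.25571939, tolerance = 0.01)
  # both separate the two populations
  expect_gt(otsuThreshold(vals), max(0.2, min(vals)))
  expect_lt(otsuThreshold(vals), 0.65)
  expect_true(is.na(otsuThreshold(rep(0.5, 100))))
  expect_true(is.na(yenThreshold(rep(2, 10))))
})

test_that("dataset-max normalisation and orientation averaging behave as specified", {
  expect_equal(normalizeToDatasetMax(c(2, 4)), c(50, 100))
  expect_equal(normalizeToDatasetMax(7), 100)
  expect_equal(normalizeToDatasetMax(c(0, 0, 5)), c(0, 0, 100))
  expect_warning(z <- normalizeToDatasetMax(c(0, 0)), "zero")
  expect_equal(z, c(0, 0))
  expect_error(normalizeToDatasetMax(numeric(0)))
  expect_error(normalizeToDatasetMax(c(NA_real_, NA_real_)))

  expect_equal(combineOrientations(60, 40), 50)
  expect_equal(combineOrientations(80, NA), 80)
  expect_equal(combineOrientations(0, 0), 0)
  expect_true(is.na(combineOrientations(NA_real_, NA_real_)))
})

test_that("segmentation requires at least one usable ROI", {
  r <- renderIhcSlide(5, "nf70_dab", seed = 2, imageSize = c(64, 64),
                      nFascicles = 1L)
  bad <- list(FascicleROI(roiPolygon(r$rois[[1]]), usable = FALSE))
  expect_error(nf70AreaFraction(r$image, bad), "usable")
})
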