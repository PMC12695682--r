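test_that("noiseless renders give exact fiber and degenerating counts", {
  s <- renderSemithin(40, 7, seed = 13, imageSize = c(240, 320),
                      micronsPerPixel = 1, noiseSd = 0)
  det <- detectFibers(s$image, s$rois)
  expect_equal(sum(det$classification == "healthy_myelinated"), 40L)
  expect_equal(sum(det$classification == "degenerating"), 7L)

  blank <- renderSemithin(0, 0, seed = 13, imageSize = c(96, 96),
                          micronsPerPixel = 1, noiseSd = 0)
  expect_equal(nrow(detectFibers(blank$image, blank$rois)), 0L)
  expect_error(detectFibers(s$image, list()), "ROI")
})

test_that("detection under default noise stays within 10% at moderate density", {
  for (seed in c(2, 5)) {
    s <- renderSemithin(30, 4, seed = seed, imageSize = c(240, 320),
                        micronsPerPixel = 1)
    det <- detectFibers(s$image, s$rois)
    expect_lte(abs(sum(det$classification == "healthy_myelinated") - 30), 3)
  }
})

test_that("fiber density arithmetic excludes unusable fascicles", {
  # rectangle ROIs with exact polygon areas: 400 x 250 px at 1 um/px
  # = 0.1 mm^2 usable; unusable fascicle holds 99 fibers that are ignored
  usable <- rectRoi(0, 0, 400, 250, label = "A")
  excl <- rectRoi(0, 260, 400, 510, label = "B", usable = FALSE)
  det <- data.frame(
    fascicle_label = c(rep("A", 30), rep("B", 99)),
    classification = "healthy_myelinated"
  )
  res <- fiberDensity(det, list(usable, excl), micronsPerPixel = 1)
  expect_equal(res@fiberDensity, 300)
  expect_equal(res@excludedFascicles, 1L)
  expect_equal(res@usableFascicles, 1L)

  # 50 fibers over 0.1 mm^2 -> 500 /mm^2 ; zero fibers -> 0
  det50 <- data.frame(fascicle_label = rep("A", 50),
                      classification = "healthy_myelinated")
  expect_equal(fiberDensity(det50, list(usable), 1)@fiberDensity, 500)
  none <- det50[0, ]
  expect_equal(fiberDensity(none, list(usable), 1)@fiberDensity, 0)
  expect_error(fiberDensity(det50, list(excl), 1), "usable")
})

test_that("degenerating counts use the conservative tie-break at the threshold", {
  # 7 degenerating in 0.05 mm^2 -> 140 /mm^2
  roi <- rectRoi(0, 0, 250, 200)  # 50000 px = 0.05 mm^2 at 1 um/px
  det <- data.frame(fascicle_label = rep("R", 9),
                    classification = c(rep("degenerating", 7),
                                       rep("healthy_myelinated", 2)))
  res <- countDegenerating(det, list(roi), 1)
  expect_equal(res$degen_density_mm2, 140)
  expect_equal(res$degen_count, 7L)

  # a profile whose lumen fraction equals the threshold counts as healthy
  s <- renderSemithin(15, 0, seed = 17, imageSize = c(200, 200),
                      micronsPerPixel = 1, noiseSd = 0)
  d0 <- detectFibers(s$image, s$rois)
  atThr <- min(d0$lumen_fraction)
  dEq <- detectFibers(s$image, s$rois,
                      fiberParams(lumenFractionThreshold = atThr))
  expect_equal(sum(dEq$classification == "degenerating"), 0L)
  dAbove <- detectFibers(s$image, s$rois,
                         fiberParams(lumenFractionThreshold =
                                       atThr + 1e-6))
  expect_gte(sum(dAbove$classification == "degenerating"), 1L)

  # degenerating count is non-increasing as the threshold decreases
  thrs <- c(0.3, 0.2, 0.1, 0.05)
  counts <- vapply(thrs, function(th)
    sum(detectFibers(s$image, s$rois,
                     fiberParams(lumenFractionThreshold = th))$classification ==
          "degenerating"), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("density is invariant to splitting a covering ROI in two", {
  s <- renderSemithin(25, 3, seed = 23, imageSize = c(200, 300),
                      micronsPerPixel = 1, noiseSd = 0)
  whole <- rectRoi(0, 0, 299, 199, label = "W")
  left <- rectRoi(0, 0, 150, 199, label = "L")
  right <- rectRoi(150, 0, 299, 199, label = "R")
  d1 <- detectFibers(s$image, list(whole))
  d2 <- detectFibers(s$image, list(left, right))
  r1 <- fiberDensity(d1, list(whole), 1)
  r2 <- fiberDensity(d2, list(left, right), 1)
  expect_equal(r1@fiberCount, r2@fiberCount)
  expect_equal(r1@fiberDensity, r2@fiberDensity, tolerance = 0.01)
})

test_that("ovoid fractions are exact on rendered strips", {
  r <- renderTeasedFibers(25, 5, seed = 3, noiseSd = 0)
  res <- ovoidFraction(r$image)
  expect_equal(res$ovoid_fraction, 0.2)
  expect_equal(res$assessable_fibers, 25L)

  r0 <- renderTeasedFibers(20, 0, seed = 4, noiseSd = 0)
  expect_equal(ovoidFraction(r0$image)$ovoid_fraction, 0)

  rAll <- renderTeasedFibers(30, 30, seed = 5)
  expect_equal(suppressWarnings(ovoidFraction(rAll$image))$ovoid_fraction, 1)

  rFew <- renderTeasedFibers(19, 4, seed = 6)
  expect_warning(resFew <- ovoidFraction(rFew$image), "19 assessable")
  expect_equal(resFew$assessable_fibers, 19L)

  blank <- SlideImage(array(230, dim = c(40, 200, 3)), 0.5,
                      orientation = "longitudinal", stain = "teased_ppd")
  expect_error(ovoidFraction(blank), "assessable")
})
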