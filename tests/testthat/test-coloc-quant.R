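# Confocal quantification: 8-bit conversion, colocalization, edge ROIs,
# normalized areas, particles, ratiometrics.

test_that("8-bit conversion is a clipped, half-up-rounded linear map", {
  m <- matrix(0:255, 16, 16)
  expect_equal(unclass(convert8bit(m, range = c(0, 255))), m,
               ignore_attr = TRUE)
  expect_true(all(convert8bit(matrix(7, 3, 3), range = c(7, 99)) == 0))

  ramp <- matrix(seq(0, 65535, length.out = 64), 8, 8)
  conv <- convert8bit(ramp, range = c(0, 65535))
  expect_equal(unclass(conv), floor(ramp * 255 / 65535 + 0.5),
               ignore_attr = TRUE)

  # idempotent on an already converted channel
  again <- convert8bit(conv, range = c(0, 255))
  expect_equal(unclass(again), unclass(conv), ignore_attr = TRUE)

  expect_error(convert8bit(m, range = c(10, 10)), "degenerate")
})

test_that("colocalization mask matches pixelwise evaluation of the rule", {
  cp <- ColocParams(tA = 20, tB = 20, rho = 0.10)
  a <- matrix(200, 3, 3)
  m <- colocMask(a, a, cp)
  expect_true(all(m))  # identical channels above threshold: ratio 1

  expect_false(any(colocMask(a, matrix(0, 3, 3), cp)))

  a4 <- matrix(c(200, 15, 60, 0, 120, 200, 30, 90,
                 250, 10, 45, 255, 5, 5, 70, 140), 4, 4)
  b4 <- matrix(c(25, 200, 6, 80, 110, 19, 200, 90,
                 24, 10, 46, 26, 200, 4, 300, 13), 4, 4)
  expect_equal(unclass(colocMask(a4, b4, cp)),
               bruteColoc(a4, b4, 20, 20, 0.10), ignore_attr = TRUE)

  expect_error(colocMask(a, matrix(0, 2, 2), cp), "shapes")
})

test_that("raising the mutual fraction or thresholds shrinks the mask", {
  set.seed(13)
  a <- matrix(sample(0:255, 400, TRUE), 20, 20)
  b <- matrix(sample(0:255, 400, TRUE), 20, 20)
  prev <- NULL
  for (rho in c(0.05, 0.1, 0.3, 0.6, 0.9)) {
    m <- colocMask(a, b, ColocParams(tA = 10, tB = 10, rho = rho))
    if (!is.null(prev)) expect_true(all(prev | !m))  # m subset of prev
    prev <- m
  }
  low <- colocMask(a, b, ColocParams(tA = 10, tB = 10))
  high <- colocMask(a, b, ColocParams(tA = 80, tB = 80))
  expect_true(all(low | !high))
  # coloc area never exceeds either marker area
  expect_lte(sum(low), min(sum(a >= 10), sum(b >= 10)))
})

test_that("edge ROI sampling places the requested regions on a disc", {
  px <- 2
  n <- 520
  cx <- ((1:n) - 0.5) * px
  mask <- outer(cx - 520, cx - 520, function(a, b) a^2 + b^2) <= 500^2

  rois <- sampleEdgeROIs(mask, n = 10, diameter = 100, pixelSize = px,
                         seed = 42)
  expect_equal(nrow(rois), 10)
  # pairwise non-overlap
  d <- as.matrix(dist(rois[, c("cx_um", "cy_um")]))
  expect_true(all(d[upper.tri(d)] >= 100))
  # fully inside the section
  r <- sqrt((rois$cx_um - 520)^2 + (rois$cy_um - 520)^2)
  expect_true(all(r + 50 <= 500 + px))

  rois2 <- sampleEdgeROIs(mask, n = 10, diameter = 100, pixelSize = px,
                          seed = 42)
  expect_identical(rois, rois2)

  # section smaller than one ROI radius: zero regions, explicit warning
  tiny <- outer(cx - 520, cx - 520, function(a, b) a^2 + b^2) <= 30^2
  expect_warning(r0 <- sampleEdgeROIs(tiny, n = 10, diameter = 100,
                                      pixelSize = px, seed = 1),
                 "placed 0 of 10")
  expect_equal(nrow(r0), 0)
})

.roiPair <- function(dims, r1, r2) {
  cx <- (seq_len(dims[1]) - 0.5); cy <- (seq_len(dims[2]) - 0.5)
  s1 <- outer(cx - r1[1], cy - r1[2], function(a, b) a^2 + b^2) <= (r1[3] / 2)^2
  s2 <- outer(cx - r2[1], cy - r2[2], function(a, b) a^2 + b^2) <= (r2[3] / 2)^2
  s1 | s2
}

test_that("areas are DAPI-normalized with flagged missing values", {
  px <- 0.1563257
  dapi <- matrix(FALSE, 20, 20); dapi[1:10, 1:4] <- TRUE   # 40 px
  mask <- matrix(FALSE, 20, 20); mask[1:5, 1:2] <- TRUE    # 10 px
  res <- normalizedArea(mask, dapi, pixelSize = px)
  expect_equal(res$area_um2, 10 * px^2)
  expect_equal(res$dapi_area_um2, 40 * px^2)
  expect_equal(res$ratio, 0.25)

  expect_equal(normalizedArea(dapi, dapi, pixelSize = px)$ratio, 1)
  expect_equal(normalizedArea(matrix(FALSE, 20, 20), dapi,
                              pixelSize = px)$ratio, 0)

  expect_warning(
    bad <- normalizedArea(mask, matrix(FALSE, 20, 20), pixelSize = px),
    "zero DAPI"
  )
  expect_true(is.na(bad$ratio) && bad$flagged)

  # additivity over disjoint ROIs
  big <- matrix(TRUE, 40, 40)
  m2 <- matrix(runif(1600) < 0.3, 40, 40)
  roi1 <- c(10, 10, 16); roi2 <- c(30, 30, 16)  # disjoint circles (um, px=1)
  a1 <- normalizedArea(m2, big, roi1, pixelSize = 1)
  a2 <- normalizedArea(m2, big, roi2, pixelSize = 1)
  both <- sum(m2[.roiPair(dim(m2), roi1, roi2)])
  expect_equal(a1$area_um2 + a2$area_um2, both)
})

test_that("particle labeling matches the flood-fill oracle", {
  diag2 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(max(labelParticles(diag2, 8)), 1)
  expect_equal(max(labelParticles(diag2, 4)), 2)

  set.seed(19)
  for (k in 1:10) {
    m <- matrix(runif(64) < 0.4, 8, 8)
    for (conn in c(4, 8)) {
      expect_true(sameLabeling(labelParticles(m, conn), bruteLabel(m, conn)))
    }
  }
})

test_that("particle statistics count, size and filter components", {
  px <- 0.1563257
  m <- matrix(0, 8, 8); m[1:3, 1] <- 1; m[6:8, 5] <- 1
  ps <- particleStats(m, pixelSize = px)
  expect_equal(ps$count, 2L)
  expect_equal(sort(ps$sizes_um2), rep(3 * px^2, 2))

  expect_equal(particleStats(matrix(0, 5, 5), pixelSize = px)$count, 0L)

  # minimum-size filter drops the singleton
  m[5, 8] <- 1
  ps2 <- particleStats(m, ColocParams(minParticleSize = 2), pixelSize = px)
  expect_equal(ps2$count, 2L)
  # total particle size never exceeds the mask area
  expect_lte(sum(ps2$sizes_px), sum(m > 0))
})

test_that("ratiometric particle means exclude below-floor pixels", {
  px <- 1
  num <- matrix(4, 3, 3); den <- matrix(2, 3, 3)
  src <- matrix(TRUE, 3, 3)
  r <- ratiometricParticles(num, den, src, pixelSize = px)
  expect_equal(r$particles$mean_ratio, 2)
  expect_equal(r$excludedPixelCount, 0)

  r1 <- ratiometricParticles(den, den, src, pixelSize = px)
  expect_equal(r1$particles$mean_ratio, 1)

  # one below-floor pixel: hand-computed mean over the remaining eight
  num2 <- matrix(c(2, 4, 6, 8, 10, 12, 14, 16, 18), 3, 3)
  den2 <- matrix(2, 3, 3); den2[2, 2] <- 0
  r2 <- ratiometricParticles(num2, den2, src,
                             ColocParams(ratioFloor = 1), pixelSize = px)
  expect_equal(r2$particles$mean_ratio,
               mean((num2[den2 >= 1]) / 2))
  expect_equal(r2$particles$n_excluded, 1)
  expect_equal(r2$excludedPixelCount, 1)

  # particle with every pixel excluded: NA mean, flagged
  den3 <- matrix(0, 3, 3)
  r3 <- ratiometricParticles(num2, den3, src, pixelSize = px)
  expect_true(is.na(r3$particles$mean_ratio))
  expect_true(r3$particles$flagged)
})

test_that("phantom sections recover their configured overlap fraction", {
  pp <- ConfocalPhantomParams(sectionRadius = 60, rimWidth = 15, nNuclei = 20,
                              nPuncta = 80, overlapFraction = 0.5, seed = 101)
  ph <- simulateConfocalSection(pp)
  cp <- ColocParams(tA = 25, tB = 25)
  cm <- colocMask(ph$image[, , "markerA"], ph$image[, , "markerB"], cp)
  mb <- ph$image[, , "markerB"] >= 25
  frac <- sum(cm) / sum(mb)
  truthFrac <- mean(ph$truth$overlapped[ph$truth$channel == "markerB"])
  expect_lt(abs(frac - truthFrac), 0.03)
})

test_that("quantifySection produces coherent per-ROI results", {
  pp <- ConfocalPhantomParams(sectionRadius = 60, rimWidth = 20, nNuclei = 30,
                              nPuncta = 60, overlapFraction = 0.7, seed = 5)
  ph <- simulateConfocalSection(pp)
  q <- quantifySection(ph$image, ColocParams(tA = 25, tB = 25),
                       nRois = 6, roiDiameter = 25, seed = 2)
  expect_equal(nrow(q$perRoi), 6)
  expect_true(all(q$perRoi$area_coloc <=
                  pmin(q$perRoi$area_A, q$perRoi$area_B) + 1e-9))
  expect_true(all(q$perRoi$area_dapi > 0))
  expect_true(all(q$perRoi$ratio_coloc >= 0))
})
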