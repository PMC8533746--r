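# Super-resolution per-synapse analysis: projection, blur, centroids,
# geometry, profiles, classification, aggregation.

test_that("projection is an element-wise maximum and r = 0 blur is identity", {
  g <- matrix(runif(25), 5, 5)
  expect_identical(maxProject(g), g)
  expect_equal(gaussianBlur(g, 0), g)

  set.seed(1)
  stack <- array(runif(50), c(5, 5, 2))
  proj <- maxProject(stack)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(proj[i, j], max(stack[i, j, 1], stack[i, j, 2]))
  }
  expect_true(all(maxProject(array(0, c(4, 4, 3))) == 0))
})

test_that("Gaussian blur matches brute-force convolution", {
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  expect_equal(gaussianBlur(imp, 0.8), bruteConv2(imp, bruteGaussKernel(0.8)),
               tolerance = 1e-10, ignore_attr = TRUE)

  set.seed(7)
  img <- matrix(runif(49), 7, 7)
  for (r in c(0.5, 1, 2)) {
    expect_equal(gaussianBlur(img, r), bruteConv2(img, bruteGaussKernel(r)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("projectAndBlur preprocesses all three channels", {
  stacks <- list(
    pre = array(runif(32), c(4, 4, 2)),
    post = matrix(runif(16), 4, 4),
    matrix = matrix(0, 4, 4)
  )
  out <- projectAndBlur(stacks, CleftClassParams(blurRadius = 0))
  expect_equal(out$pre, pmax(stacks$pre[, , 1], stacks$pre[, , 2]))
  expect_equal(out$post, stacks$post)
  expect_true(all(out$matrix == 0))
})

test_that("centroids match the weighted-mean oracle", {
  # symmetric blob: centroid at its center
  g <- bruteGaussKernel(1.5)
  c0 <- channelCentroid(g, pixelSize = 1)
  expect_equal(unname(c0), rep(nrow(g) / 2, 2), tolerance = 1e-9)

  # two equal pixels symmetric about the grid center
  h <- matrix(0, 5, 5); h[1, 3] <- 2; h[5, 3] <- 2
  expect_equal(unname(channelCentroid(h, pixelSize = 1)[1]), 2.5)

  set.seed(11)
  m <- matrix(runif(36), 6, 6)
  expect_equal(unname(channelCentroid(m, pixelSize = 3, origin = c(10, -5))),
               bruteCentroid(m, 3, c(10, -5)), tolerance = 1e-12)

  expect_true(all(is.na(channelCentroid(matrix(0, 4, 4)))))
})

test_that("cleft geometry follows from the marker centroids", {
  geo <- cleftGeometry(c(0, 0), c(100, 0))
  expect_equal(geo$axis, c(1, 0))
  expect_equal(geo$midpoint, c(50, 0))
  expect_equal(geo$separation, 100)

  rev <- cleftGeometry(c(100, 0), c(0, 0))
  expect_equal(rev$axis, -geo$axis)
  expect_equal(rev$midpoint, geo$midpoint)
  expect_equal(rev$separation, geo$separation)

  expect_equal(cleftGeometry(c(0, 0), c(30, 40))$separation, 50)
  expect_error(cleftGeometry(c(5, 5), c(5, 5)), "coincide")
})

test_that("intensity profiles sample perpendicular strips along the axis", {
  # uniform image: constant profile
  u <- matrix(2.5, 10, 10)
  geo <- cleftGeometry(c(30, 50), c(70, 50))
  p <- intensityProfiles(list(ch = u), geo, width = 3, pixelSize = 10,
                         margin = 10)
  expect_true(all(abs(p$ch - 2.5) < 1e-12))

  # Gaussian blob on the axis peaks at its axial coordinate
  g <- matrix(0, 21, 21); g[13, 11] <- 1
  g <- gaussianBlur(g, 1.5)
  geo2 <- cleftGeometry(c(5.5, 10.5), c(15.5, 10.5))  # axis along x, y = 10.5
  p2 <- intensityProfiles(list(ch = g), geo2, width = 3, pixelSize = 1,
                          margin = 3)
  peakPos <- p2$position_nm[which.max(p2$ch)]
  expect_lt(abs((5.5 + peakPos) - 12.5), 0.5)  # blob x center is 12.5

  # axis-aligned 8x8 case against hand-enumerated strip means
  set.seed(3)
  m <- matrix(runif(64), 8, 8)
  geo3 <- cleftGeometry(c(2.5, 4), c(6.5, 4))  # y = 4 is the j = 4/5 boundary
  p3 <- intensityProfiles(list(ch = m), geo3, width = 3, pixelSize = 1,
                          margin = 0)
  # samples at x = 2.5 + t land mid-pixel only for integer t; check those
  for (t in c(0, 1, 2, 3, 4)) {
    i <- 3 + t  # x = 2.5 + t is the center of pixel i = t + 3
    manual <- mean(c(
      (m[i, 3] + m[i, 4]) / 2,   # offset -1: y = 3, between centers 2.5 / 3.5
      (m[i, 4] + m[i, 5]) / 2,   # offset 0: y = 4
      (m[i, 5] + m[i, 6]) / 2    # offset +1: y = 5
    ))
    k <- which(abs(p3$position_nm - t) < 1e-9)
    expect_equal(p3$ch[k], manual, tolerance = 1e-12)
  }

  expect_error(
    intensityProfiles(list(ch = m), cleftGeometry(c(-20, 4), c(30, 4)),
                      width = 1, pixelSize = 1),
    "outside"
  )
})

test_that("cleft classification applies the printed distance rules", {
  expect_equal(as.character(classifyCleftLocalization(40, 45, TRUE)),
               "IN_CLEFT")
  expect_equal(as.character(classifyCleftLocalization(60, 95, TRUE)),
               "NEAR_CLEFT")
  expect_equal(as.character(classifyCleftLocalization(30, 160, TRUE)),
               "PRE_PREFERENTIAL")
  expect_equal(as.character(classifyCleftLocalization(160, 30, TRUE)),
               "POST_PREFERENTIAL")
  expect_equal(as.character(classifyCleftLocalization(123, 456, FALSE)),
               "ABSENT")
  # gap case: one distance under 50, the other between 50 and 100
  expect_equal(as.character(classifyCleftLocalization(30, 80, TRUE)),
               "NEAR_CLEFT")
  # printed bounds are strict: boundary values fall through
  expect_equal(as.character(classifyCleftLocalization(50, 50, TRUE)),
               "NEAR_CLEFT")
  expect_equal(as.character(classifyCleftLocalization(20, 120, TRUE)),
               "NEAR_CLEFT")  # difference exactly 100 is not preferential
  expect_equal(as.character(classifyCleftLocalization(20, 121, TRUE)),
               "PRE_PREFERENTIAL")
  expect_error(classifyCleftLocalization(-1, 10, TRUE), "non-negative")
})

test_that("classification is total and label-swap symmetric", {
  set.seed(23)
  d1 <- runif(500, 0, 400); d2 <- runif(500, 0, 400)
  pres <- runif(500) < 0.9
  cls <- classifyCleftLocalization(d1, d2, pres)
  expect_true(all(cls %in% fiveClasses))

  swapped <- classifyCleftLocalization(d2, d1, pres)
  mapSwap <- c(
    IN_CLEFT = "IN_CLEFT", NEAR_CLEFT = "NEAR_CLEFT", ABSENT = "ABSENT",
    PRE_PREFERENTIAL = "POST_PREFERENTIAL",
    POST_PREFERENTIAL = "PRE_PREFERENTIAL"
  )
  expect_identical(as.character(swapped), unname(mapSwap[cls]))
})

test_that("compartment assignment counts sides within 100 nm", {
  expect_equal(classifyCompartment(80, 90), "BOTH")
  expect_equal(classifyCompartment(40, 250), "PRE_ONLY")
  expect_equal(classifyCompartment(250, 40), "POST_ONLY")
  expect_equal(classifyCompartment(150, 150), "NEITHER")
  expect_equal(classifyCompartment(100, 100), "BOTH")  # inclusive bound
  expect_error(classifyCompartment(-5, 10), "non-negative")
})

test_that("distributions aggregate to exact percentages", {
  d <- aggregateDistribution(rep("IN_CLEFT", 10))
  expect_equal(d$percent[d$class == "IN_CLEFT"], 100)
  expect_equal(sum(d$percent), 100)

  d2 <- aggregateDistribution(c("IN_CLEFT", "IN_CLEFT", "NEAR_CLEFT", "ABSENT"))
  expect_equal(d2$percent[match(c("IN_CLEFT", "NEAR_CLEFT", "ABSENT"),
                                d2$class)], c(50, 25, 25))
  expect_identical(attr(d2, "n"), 4L)
  expect_equal(sum(d2$count), 4)

  set.seed(2)
  x <- sample(fiveClasses, 137, replace = TRUE)
  expect_equal(sum(aggregateDistribution(x)$percent), 100)
  expect_error(aggregateDistribution(character(0)), "no measurements")
})

test_that("the full per-synapse chain recovers zero-noise geometry", {
  p <- SynapseSimParams(separation = 80, matrixOffset = 0, matrixLateralSD = 0,
                        clusterSD = 0, nEmittersPerChannel = 50,
                        blinksPerEmitter = 1, precisionSD = 0, seed = 6)
  sim <- simulateSynapse(p)
  m <- analyzeSynapse(SynapseROI(localizations = sim$table, pixelSize = 2))
  expect_equal(cleftClass(m), "IN_CLEFT")
  expect_equal(unname(cleftDistances(m)[c("dPre", "dPost")]), c(40, 40),
               tolerance = 0.05)  # rendering/blur discretization only
  expect_equal(compartmentClass(m), "BOTH")

  # empty matrix channel fails the presence criterion
  simA <- simulateSynapse(SynapseSimParams(matrixPresent = FALSE, seed = 6))
  mA <- analyzeSynapse(SynapseROI(localizations = simA$table, pixelSize = 5))
  expect_equal(cleftClass(mA), "ABSENT")
  expect_false(mA@present)
})

test_that("swapping pre/post roles swaps the preferential call", {
  sim <- simulateSynapse(presetSimParams("PRE_PREFERENTIAL", seed = 17))
  roiFwd <- SynapseROI(localizations = sim$table, pixelSize = 5)
  roiRev <- SynapseROI(localizations = sim$table, pixelSize = 5,
                       channelRoles = c(pre = "post", post = "pre",
                                        matrix = "matrix"))
  mF <- analyzeSynapse(roiFwd)
  mR <- analyzeSynapse(roiRev)
  expect_equal(cleftClass(mF), "PRE_PREFERENTIAL")
  expect_equal(cleftClass(mR), "POST_PREFERENTIAL")
  expect_equal(mF@dPre, mR@dPost, tolerance = 1e-9)
  expect_equal(mF@dPost, mR@dPre, tolerance = 1e-9)
  expect_equal(compartmentClass(mF), "PRE_ONLY")
  expect_equal(compartmentClass(mR), "POST_ONLY")
})

test_that("distances and classes are rigid-motion invariant", {
  sim <- simulateSynapse(presetSimParams("NEAR_CLEFT", seed = 29))
  df <- locData(sim$table)

  measure <- function(df) {
    tab <- LocalizationTable(df)
    cen <- function(ch) channelCentroid(tab, channel = ch)
    geo <- cleftGeometry(cen("pre"), cen("post"))
    m <- cen("matrix")
    c(
      dPre = sqrt(sum((m - cen("pre"))^2)),
      dPost = sqrt(sum((m - cen("post"))^2)),
      sep = geo$separation
    )
  }
  base <- measure(df)

  phi <- 0.7; R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  xy <- as.matrix(df[, c("x_nm", "y_nm")]) %*% t(R)
  df2 <- df
  df2$x_nm <- xy[, 1] + 1234.5
  df2$y_nm <- xy[, 2] - 987.6
  expect_equal(measure(df2), base, tolerance = 1e-9)

  # the rendered-image route is pixel-quantized: invariance holds to pixel scale
  m1 <- analyzeSynapse(SynapseROI(localizations = LocalizationTable(df),
                                  pixelSize = 5))
  m2 <- analyzeSynapse(SynapseROI(localizations = LocalizationTable(df2),
                                  pixelSize = 5))
  expect_equal(cleftClass(m1), cleftClass(m2))
  expect_lt(abs(m1@dPre - m2@dPre), 2 * 5)
  expect_lt(abs(m1@dPost - m2@dPost), 2 * 5)
})

test_that("recovery accuracy does not improve with worse precision", {
  accuracyAt <- function(precision, baseSeed) {
    classes <- rep(fiveClasses, each = 12)
    batch <- simulateSynapseBatch(classes, baseSeed = baseSeed,
                                  precisionSD = precision)
    res <- analyzeSynapses(batch, pixelSize = 5)
    truth <- vapply(batch, function(b) truthLabel(b$truth), character(1))
    mean(res$cleft_class == truth)
  }
  accs <- c(accuracyAt(5, 300), accuracyAt(40, 600), accuracyAt(120, 900))
  expect_true(all(diff(accs) <= 0))
  expect_gt(accs[1], 0.9)
})
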