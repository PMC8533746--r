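# Ground-truth generators: synapse localization clouds and confocal phantoms.

test_that("identical parameters and seed give bit-identical synapses", {
  p <- SynapseSimParams(separation = 120, matrixOffset = 30, seed = 77)
  s1 <- simulateSynapse(p)
  s2 <- simulateSynapse(p)
  expect_identical(locData(s1$table), locData(s2$table))
  expect_identical(serialize(s1$truth, NULL), serialize(s2$truth, NULL))
  s3 <- simulateSynapse(SynapseSimParams(separation = 120, matrixOffset = 30,
                                         seed = 78))
  expect_false(identical(locData(s1$table), locData(s3$table)))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(314)
  before <- .Random.seed
  invisible(simulateSynapse(SynapseSimParams(seed = 9)))
  expect_identical(.Random.seed, before)
})

test_that("absent matrix channel yields zero rows and an ABSENT label", {
  sim <- simulateSynapse(SynapseSimParams(matrixPresent = FALSE, seed = 4))
  df <- locData(sim$table)
  expect_identical(sum(df$channel == "matrix"), 0L)
  expect_identical(truthLabel(sim$truth), "ABSENT")
})

test_that("zero-noise clouds collapse onto the true channel centers", {
  p <- SynapseSimParams(separation = 100, matrixOffset = 20,
                        matrixLateralSD = 0, clusterSD = 0,
                        nEmittersPerChannel = 25, blinksPerEmitter = 1,
                        precisionSD = 0, seed = 12)
  sim <- simulateSynapse(p)
  truth <- sim$truth
  for (ch in c("pre", "post", "matrix")) {
    emp <- channelCentroid(sim$table, channel = ch)
    expect_equal(unname(emp), unname(truth@trueCentroids[ch, c("x", "y")]),
                 tolerance = 1e-12)
  }
  expect_equal(truth@dPre, 70)  # matrix 20 nm past the midpoint of 100 nm
  expect_equal(truth@dPost, 30)
})

test_that("empirical centroid error respects the standard-error bound", {
  # localization noise only: 200 blinks at precision SD 15 nm per axis
  errs <- sapply(1:100, function(seed) {
    p <- SynapseSimParams(separation = 150, clusterSD = 0,
                          matrixLateralSD = 0, nEmittersPerChannel = 200,
                          blinksPerEmitter = 1, precisionSD = 15, seed = seed)
    sim <- simulateSynapse(p)
    emp <- channelCentroid(sim$table, channel = "pre")
    abs(emp - sim$truth@trueCentroids["pre", c("x", "y")])
  })
  bound <- 3 * 15 / sqrt(200)
  expect_lt(mean(errs[1, ]), bound)
  expect_lt(mean(errs[2, ]), bound)
})

test_that("ground-truth labels are consistent with the classifier", {
  set.seed(55)
  for (i in 1:30) {
    p <- SynapseSimParams(
      separation = runif(1, 40, 400),
      matrixOffset = runif(1, -200, 200),
      matrixLateralSD = runif(1, 0, 40),
      matrixPresent = runif(1) < 0.8,
      seed = 1000 + i
    )
    truth <- simulateSynapse(p)$truth
    expected <- classifyCleftLocalization(
      dPre = if (p@matrixPresent) truth@dPre else 0,
      dPost = if (p@matrixPresent) truth@dPost else 0,
      present = p@matrixPresent
    )
    expect_identical(truthLabel(truth), as.character(expected))
  }
})

test_that("rendering conserves counts and matches a binning oracle", {
  sim <- simulateSynapse(SynapseSimParams(seed = 21))
  g <- renderLocalizations(sim$table, pixelSize = 10, channel = "pre")
  expect_equal(sum(g), sum(locData(sim$table)$channel == "pre"))

  # single localization at the origin
  one <- LocalizationTable(data.frame(
    channel = "m", x_nm = 0, y_nm = 0, z_nm = 0, frame = 1, photons = 1
  ))
  g1 <- renderLocalizations(one, pixelSize = 5, channel = "m")
  expect_equal(sum(g1 != 0), 1)
  expect_equal(max(g1), 1)

  # hand-enumerated binning of 4 points on a fixed 3x3 grid
  x <- c(0.5, 1.5, 2.9, 0.1); y <- c(0.5, 0.5, 2.1, 2.9)
  tab <- LocalizationTable(data.frame(
    channel = "m", x_nm = x, y_nm = y, z_nm = 0, frame = 1, photons = 1
  ))
  g3 <- renderLocalizations(tab, pixelSize = 1, channel = "m",
                            xlim = c(0, 3), ylim = c(0, 3))
  expect_equal(unclass(g3), bruteBin(x, y, c(0, 3), c(0, 3), 1, 3, 3),
               ignore_attr = TRUE)

  expect_warning(
    gz <- renderLocalizations(one, pixelSize = 5, channel = "absent-channel"),
    "no localizations"
  )
  expect_true(all(gz == 0))
})

phantomParams <- function(f, seed, nPuncta = 80) {
  ConfocalPhantomParams(
    sectionRadius = 60, rimWidth = 15, nNuclei = 20, nPuncta = nPuncta,
    overlapFraction = f, seed = seed
  )
}

test_that("confocal phantoms are deterministic and 8-bit", {
  p1 <- simulateConfocalSection(phantomParams(0.5, seed = 31))
  p2 <- simulateConfocalSection(phantomParams(0.5, seed = 31))
  expect_identical(p1$image, p2$image)
  expect_identical(p1$truth, p2$truth)
  expect_true(all(p1$image >= 0 & p1$image <= 255))
  expect_identical(dimnames(p1$image)[[3]], c("dapi", "markerA", "markerB"))
})

test_that("full overlap and zero overlap bound the colocalized area", {
  cp <- ColocParams(tA = 25, tB = 25)
  ph1 <- simulateConfocalSection(phantomParams(1, seed = 8))
  m1 <- colocMask(ph1$image[, , "markerA"], ph1$image[, , "markerB"], cp)
  b1 <- ph1$image[, , "markerB"] >= 25
  expect_equal(sum(m1), sum(b1))  # coloc area equals the marker-B punctum area

  ph0 <- simulateConfocalSection(phantomParams(0, seed = 8))
  m0 <- colocMask(ph0$image[, , "markerA"], ph0$image[, , "markerB"], cp)
  expect_equal(sum(m0), 0)
})

test_that("overlapped-punctum counts follow the configured Bernoulli rate", {
  counts <- vapply(1:20, function(seed) {
    ph <- simulateConfocalSection(phantomParams(0.5, seed = seed,
                                                nPuncta = 100))
    sum(ph$truth$overlapped[ph$truth$channel == "markerB"])
  }, numeric(1))
  # mean of 20 Binomial(100, 0.5) draws: 99% interval for the mean is
  # 50 +/- 2.576 * 5 / sqrt(20)
  expect_gt(mean(counts), 50 - 2.576 * 5 / sqrt(20))
  expect_lt(mean(counts), 50 + 2.576 * 5 / sqrt(20))
})

test_that("parameter validation rejects impossible geometries", {
  expect_error(SynapseSimParams(separation = 0), "separation")
  expect_error(SynapseSimParams(nEmittersPerChannel = -5), "nEmitters")
  expect_error(ConfocalPhantomParams(rimWidth = 100, sectionRadius = 50),
               "rimWidth")
  expect_error(ConfocalPhantomParams(overlapFraction = 1.2), "overlapFraction")
})
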