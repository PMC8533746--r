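# Ground-truth synapse simulator.

#' Simulate one three-channel synapse localization cloud
#'
#' Generates a synthetic dSTORM localization table for a single excitatory
#' synapse: pre- and post-synaptic marker clusters separated by
#' \code{separation} nm along a uniformly random cleft-axis orientation, plus
#' a matrix channel centered at \code{matrixOffset} nm along the axis (0 =
#' cleft midpoint) with lateral Gaussian jitter. Emitters are isotropic
#' Gaussian clouds; each emitter blinks \code{1 + Poisson(blinksPerEmitter -
#' 1)} times and every blink carries isotropic localization error of SD
#' \code{precisionSD}. z coordinates are generated but the standard analysis
#' operates on the 2-D projection.
#'
#' The ground truth records the noiseless channel centers; its label is
#' exactly [classifyCleftLocalization()] applied to the true distances with
#' default bounds, so generator and classifier can never disagree on the
#' intended class.
#'
#' @param params a [SynapseSimParams-class].
#' @return list with \code{table} (a [LocalizationTable-class]) and
#'   \code{truth} (a [GroundTruth-class]).
#' @examples
#' sim <- simulateSynapse(SynapseSimParams(separation = 80, seed = 11))
#' truthLabel(sim$truth)
#' @export
simulateSynapse <- function(params) {
  stopifnot(is(params, "SynapseSimParams"))
  validObject(params)
  .withSeed(params@seed, {
    phi <- stats::runif(1, 0, 2 * pi)
    axis <- c(cos(phi), sin(phi), 0)
    perp <- c(-sin(phi), cos(phi), 0)
    half <- params@separation / 2
    centers <- rbind(
      pre = -half * axis,
      post = half * axis,
      matrix = params@matrixOffset * axis +
        stats::rnorm(1, 0, params@matrixLateralSD) * perp
    )
    colnames(centers) <- c("x", "y", "z")

    present <- params@matrixPresent && params@nEmittersPerChannel > 0
    if (!params@matrixPresent) centers["matrix", ] <- NA_real_

    dPre <- if (present) {
      sqrt(sum((centers["matrix", 1:2] - centers["pre", 1:2])^2))
    } else NA_real_
    dPost <- if (present) {
      sqrt(sum((centers["matrix", 1:2] - centers["post", 1:2])^2))
    } else NA_real_

    channels <- c("pre", "post", if (params@matrixPresent) "matrix")
    rows <- lapply(channels, function(ch) {
      .simulateChannel(ch, centers[ch, ], params)
    })
    df <- do.call(rbind, rows)
    rownames(df) <- NULL

    label <- classifyCleftLocalization(
      dPre = if (present) dPre else 0,
      dPost = if (present) dPost else 0,
      present = present,
      params = CleftClassParams()
    )

    truth <- new("GroundTruth",
      label = as.character(label), trueCentroids = centers,
      dPre = dPre, dPost = dPost, separation = params@separation,
      params = params
    )
    list(table = LocalizationTable(df), truth = truth)
  })
}

# Emitter cloud -> blinking localizations for one channel.
.simulateChannel <- function(channel, center, params) {
  n <- params@nEmittersPerChannel
  if (n == 0) {
    return(data.frame(
      channel = character(), x_nm = numeric(), y_nm = numeric(),
      z_nm = numeric(), frame = numeric(), photons = numeric()
    ))
  }
  emitters <- cbind(
    stats::rnorm(n, center[1], params@clusterSD),
    stats::rnorm(n, center[2], params@clusterSD),
    stats::rnorm(n, center[3], params@clusterSD)
  )
  blinks <- 1L + stats::rpois(n, params@blinksPerEmitter - 1)
  idx <- rep.int(seq_len(n), blinks)
  m <- length(idx)
  data.frame(
    channel = channel,
    x_nm = emitters[idx, 1] + stats::rnorm(m, 0, params@precisionSD),
    y_nm = emitters[idx, 2] + stats::rnorm(m, 0, params@precisionSD),
    z_nm = emitters[idx, 3] + stats::rnorm(m, 0, params@precisionSD),
    frame = sample.int(10000L, m, replace = TRUE),
    photons = round(stats::rlnorm(m, log(1000), 0.5))
  )
}

#' Geometry presets that realize each cleft class
#'
#' Returns a [SynapseSimParams-class] whose noiseless geometry yields the
#' requested ground-truth class with a comfortable margin relative to the
#' classification bounds: in-cleft uses a 70 nm separation with the matrix at
#' the midpoint (both distances 35 nm), near-cleft a 150 nm separation (both
#' 75 nm), the preferential classes a 300 nm separation with the matrix offset
#' 120 nm toward one marker (30 vs 270 nm), and ABSENT an empty matrix
#' channel.
#'
#' @param class one of IN_CLEFT, NEAR_CLEFT, PRE_PREFERENTIAL,
#'   POST_PREFERENTIAL, ABSENT.
#' @param seed RNG seed for the simulated synapse.
#' @param ... further arguments passed to [SynapseSimParams()] (noise levels,
#'   emitter counts, ...).
#' @return a [SynapseSimParams-class].
#' @examples
#' truthLabel(simulateSynapse(presetSimParams("NEAR_CLEFT", seed = 4))$truth)
#' @export
presetSimParams <- function(class = c("IN_CLEFT", "NEAR_CLEFT",
                                      "PRE_PREFERENTIAL",
                                      "POST_PREFERENTIAL", "ABSENT"),
                            seed = 1, ...) {
  class <- match.arg(class)
  geom <- switch(class,
    IN_CLEFT = list(separation = 70, matrixOffset = 0, matrixPresent = TRUE),
    NEAR_CLEFT = list(separation = 150, matrixOffset = 0, matrixPresent = TRUE),
    PRE_PREFERENTIAL = list(separation = 300, matrixOffset = -120,
                            matrixPresent = TRUE),
    POST_PREFERENTIAL = list(separation = 300, matrixOffset = 120,
                             matrixPresent = TRUE),
    ABSENT = list(separation = 150, matrixOffset = 0, matrixPresent = FALSE)
  )
  do.call(SynapseSimParams, c(geom, list(seed = seed), list(...)))
}

#' Simulate a labeled batch of synapses
#'
#' @param classes character vector of intended classes (see
#'   [presetSimParams()]); one synapse is simulated per element.
#' @param baseSeed integer; synapse i uses seed \code{baseSeed + i - 1}.
#' @param ... passed through to [presetSimParams()].
#' @return list of \code{list(table, truth)} as returned by
#'   [simulateSynapse()].
#' @examples
#' batch <- simulateSynapseBatch(c("IN_CLEFT", "ABSENT"), baseSeed = 100)
#' vapply(batch, function(b) truthLabel(b$truth), character(1))
#' @export
simulateSynapseBatch <- function(classes, baseSeed = 1, ...) {
  stopifnot(length(classes) >= 1)
  lapply(seq_along(classes), function(i) {
    simulateSynapse(presetSimParams(classes[i], seed = baseSeed + i - 1, ...))
  })
}

#' Render localizations into a 2-D count grid
#'
#' Bins the (x, y) coordinates of one channel into a pixel grid: the value of
#' pixel (i, j) is the number of localizations falling in the half-open cell
#' \code{[x0 + (i-1)s, x0 + is) x [y0 + (j-1)s, y0 + js)}. The grid total
#' therefore equals the number of in-bounds localizations.
#'
#' @param table a [LocalizationTable-class].
#' @param pixelSize nm per pixel, > 0.
#' @param channel channel label to render; NULL renders all rows.
#' @param xlim,ylim numeric(2) field of view in nm; defaults snap to the data
#'   so that every localization is in bounds.
#' @param quiet suppress the empty-channel warning.
#' @return numeric matrix (first index x, second y) with attributes
#'   \code{origin} (nm of the low corner) and \code{pixelSize}. An empty
#'   channel yields an all-zero grid with a warning.
#' @examples
#' tab <- LocalizationTable(data.frame(
#'   channel = "m", x_nm = c(1, 9), y_nm = c(1, 9), z_nm = 0,
#'   frame = 1L, photons = 1
#' ))
#' g <- renderLocalizations(tab, pixelSize = 10, channel = "m")
#' sum(g)
#' @export
renderLocalizations <- function(table, pixelSize, channel = NULL,
                                xlim = NULL, ylim = NULL, quiet = FALSE) {
  stopifnot(is(table, "LocalizationTable"))
  .assertScalarNumber(pixelSize, "pixelSize", positive = TRUE)
  df <- locData(table)
  if (!is.null(channel)) df <- df[df$channel == channel, , drop = FALSE]

  if (nrow(df) == 0 && (is.null(xlim) || is.null(ylim))) {
    if (!quiet) warning("no localizations to render; returning a 1x1 zero grid")
    g <- matrix(0, 1, 1)
    attr(g, "origin") <- c(0, 0)
    attr(g, "pixelSize") <- pixelSize
    return(g)
  }
  if (is.null(xlim)) xlim <- range(df$x_nm) + c(-1, 1) * pixelSize / 2
  if (is.null(ylim)) ylim <- range(df$y_nm) + c(-1, 1) * pixelSize / 2
  nx <- max(1L, ceiling((xlim[2] - xlim[1]) / pixelSize))
  ny <- max(1L, ceiling((ylim[2] - ylim[1]) / pixelSize))

  g <- matrix(0, nx, ny)
  if (nrow(df)) {
    ix <- floor((df$x_nm - xlim[1]) / pixelSize) + 1L
    iy <- floor((df$y_nm - ylim[1]) / pixelSize) + 1L
    ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
    if (any(ok)) {
      counts <- table(factor(ix[ok], levels = seq_len(nx)),
                      factor(iy[ok], levels = seq_len(ny)))
      g <- matrix(as.numeric(counts), nx, ny)
    }
  } else if (!quiet) {
    warning("no localizations to render; returning an all-zero grid")
  }
  attr(g, "origin") <- c(xlim[1], ylim[1])
  attr(g, "pixelSize") <- pixelSize
  g
}
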