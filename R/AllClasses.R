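#' @import methods
NULL

# ---------------------------------------------------------------------------
# Parameter classes
# ---------------------------------------------------------------------------

#' Classification parameters for the synaptic-cleft analysis
#'
#' Holds the centroid-distance bounds and preprocessing constants used by
#' [classifyCleftLocalization()] and [analyzeSynapse()]. The defaults are the
#' published procedural constants: matrix molecules whose centroid lies within
#' \code{thetaIn} = 50 nm of both synaptic-marker centroids are "in the cleft";
#' within \code{thetaNear} = 100 nm of both, "near the cleft"; a centroid
#' distance difference greater than \code{thetaDiff} = 100 nm marks
#' preferential localization to the nearer compartment. Rendered projections
#' are smoothed with a Gaussian of radius (standard deviation)
#' \code{blurRadius} = 2.00 px before centroids are taken.
#'
#' @slot thetaIn numeric(1). In-cleft bound (nm); both distances must be
#'   strictly below it.
#' @slot thetaNear numeric(1). Near-cleft bound (nm); also the per-compartment
#'   presence bound used by [classifyCompartment()].
#' @slot thetaDiff numeric(1). Preferential-difference bound (nm); strictly
#'   greater than this is preferential.
#' @slot presenceMin numeric(1). Minimum matrix-channel localization count (or
#'   integrated intensity, image route) within \code{windowRadius} of the
#'   cleft midpoint for the matrix molecule to count as present.
#' @slot windowRadius numeric(1). Radius (nm) of the presence window around
#'   the cleft midpoint.
#' @slot blurRadius numeric(1). Gaussian pre-blur radius in pixels,
#'   interpreted as the standard deviation (ImageJ Gaussian Blur convention),
#'   kernel truncated at 4 radii.
#' @slot profileWidth numeric(1). Width in pixels of the perpendicular strip
#'   averaged by [intensityProfiles()].
#'
#' @return \code{CleftClassParams()} returns a validated object.
#' @examples
#' CleftClassParams()
#' CleftClassParams(presenceMin = 5)
#' @export CleftClassParams
#' @exportClass CleftClassParams
setClass("CleftClassParams",
  representation(
    thetaIn = "numeric", thetaNear = "numeric", thetaDiff = "numeric",
    presenceMin = "numeric", windowRadius = "numeric",
    blurRadius = "numeric", profileWidth = "numeric"
  ),
  prototype(
    thetaIn = 50, thetaNear = 100, thetaDiff = 100,
    presenceMin = 10, windowRadius = 300,
    blurRadius = 2.00, profileWidth = 5
  )
)

setValidity("CleftClassParams", function(object) {
  msg <- character()
  for (s in slotNames(object)) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) {
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    }
  }
  if (length(msg)) return(msg)
  if (!(object@thetaIn > 0 && object@thetaIn < object@thetaNear)) {
    msg <- c(msg, "need 0 < thetaIn < thetaNear")
  }
  if (object@thetaDiff <= 0) msg <- c(msg, "thetaDiff must be > 0")
  if (object@presenceMin < 0) msg <- c(msg, "presenceMin must be >= 0")
  if (object@windowRadius <= 0) msg <- c(msg, "windowRadius must be > 0")
  if (object@blurRadius < 0) msg <- c(msg, "blurRadius must be >= 0")
  if (object@profileWidth < 1) msg <- c(msg, "profileWidth must be >= 1 px")
  if (length(msg)) msg else TRUE
})

#' @rdname CleftClassParams-class
#' @param thetaIn,thetaNear,thetaDiff,presenceMin,windowRadius,blurRadius,profileWidth
#'   see the slot documentation.
CleftClassParams <- function(thetaIn = 50, thetaNear = 100, thetaDiff = 100,
                             presenceMin = 10, windowRadius = 300,
                             blurRadius = 2.00, profileWidth = 5) {
  new("CleftClassParams",
    thetaIn = thetaIn, thetaNear = thetaNear, thetaDiff = thetaDiff,
    presenceMin = presenceMin, windowRadius = windowRadius,
    blurRadius = blurRadius, profileWidth = profileWidth
  )
}

#' Simulation parameters for a single synthetic synapse
#'
#' Describes the ground-truth geometry and noise model of one simulated
#' three-channel synapse: a pre-synaptic (VGLUT1-like) and a post-synaptic
#' (PSD95-like) emitter cluster separated by \code{separation} nm along a
#' randomly oriented cleft axis, plus a matrix channel (HA/HAS2/CD44-like)
#' centered at a signed axial offset from the cleft midpoint. Each emitter
#' produces \code{1 + Poisson(blinksPerEmitter - 1)} blinks (so the mean blink
#' count is \code{blinksPerEmitter} with a minimum of one), and every blink is
#' displaced by isotropic Gaussian localization error of SD \code{precisionSD}.
#'
#' @slot separation numeric(1). True pre-to-post centroid distance (nm), > 0.
#' @slot matrixOffset numeric(1). Signed axial position of the matrix-channel
#'   center (nm); 0 is the cleft midpoint, negative values lie toward the
#'   pre-synaptic marker.
#' @slot matrixLateralSD numeric(1). SD (nm) of the lateral (perpendicular)
#'   jitter applied to the matrix-channel center.
#' @slot clusterSD numeric(1). Isotropic SD (nm) of emitter positions around
#'   their channel center.
#' @slot nEmittersPerChannel integer-like numeric(1). Emitters per channel.
#' @slot blinksPerEmitter numeric(1). Mean blinks per emitter, >= 1.
#' @slot precisionSD numeric(1). Localization precision SD (nm).
#' @slot matrixPresent logical(1). When FALSE the matrix channel is empty and
#'   the ground-truth label is ABSENT.
#' @slot seed integer-like numeric(1). RNG seed; identical parameters and seed
#'   give bit-identical output.
#'
#' @return \code{SynapseSimParams()} returns a validated object.
#' @examples
#' SynapseSimParams(separation = 80, matrixOffset = 0, seed = 1)
#' @export SynapseSimParams
#' @exportClass SynapseSimParams
setClass("SynapseSimParams",
  representation(
    separation = "numeric", matrixOffset = "numeric",
    matrixLateralSD = "numeric", clusterSD = "numeric",
    nEmittersPerChannel = "numeric", blinksPerEmitter = "numeric",
    precisionSD = "numeric", matrixPresent = "logical", seed = "numeric"
  ),
  prototype(
    separation = 150, matrixOffset = 0, matrixLateralSD = 10,
    clusterSD = 50, nEmittersPerChannel = 100, blinksPerEmitter = 2,
    precisionSD = 15, matrixPresent = TRUE, seed = 1
  )
)

setValidity("SynapseSimParams", function(object) {
  msg <- character()
  num <- c(
    "separation", "matrixOffset", "matrixLateralSD", "clusterSD",
    "nEmittersPerChannel", "blinksPerEmitter", "precisionSD", "seed"
  )
  for (s in num) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) {
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    }
  }
  if (length(object@matrixPresent) != 1L || is.na(object@matrixPresent)) {
    msg <- c(msg, "'matrixPresent' must be TRUE or FALSE")
  }
  if (length(msg)) return(msg)
  if (object@separation <= 0) msg <- c(msg, "separation must be > 0")
  for (s in c("matrixLateralSD", "clusterSD", "precisionSD")) {
    if (slot(object, s) < 0) msg <- c(msg, sprintf("%s must be >= 0", s))
  }
  if (object@nEmittersPerChannel < 0 ||
      object@nEmittersPerChannel != round(object@nEmittersPerChannel)) {
    msg <- c(msg, "nEmittersPerChannel must be a non-negative integer")
  }
  if (object@blinksPerEmitter < 1) msg <- c(msg, "blinksPerEmitter must be >= 1")
  if (abs(object@seed) >= 2^31) msg <- c(msg, "seed must fit a 32-bit integer")
  if (length(msg)) msg else TRUE
})

#' @rdname SynapseSimParams-class
#' @param separation,matrixOffset,matrixLateralSD,clusterSD,nEmittersPerChannel,blinksPerEmitter,precisionSD,matrixPresent,seed
#'   see the slot documentation.
SynapseSimParams <- function(separation = 150, matrixOffset = 0,
                             matrixLateralSD = 10, clusterSD = 50,
                             nEmittersPerChannel = 100, blinksPerEmitter = 2,
                             precisionSD = 15, matrixPresent = TRUE,
                             seed = 1) {
  new("SynapseSimParams",
    separation = separation, matrixOffset = matrixOffset,
    matrixLateralSD = matrixLateralSD, clusterSD = clusterSD,
    nEmittersPerChannel = nEmittersPerChannel,
    blinksPerEmitter = blinksPerEmitter, precisionSD = precisionSD,
    matrixPresent = matrixPresent, seed = seed
  )
}

#' Parameters for a synthetic confocal spheroid section
#'
#' Describes a phantom cryosection of a cortical spheroid: a disc of tissue
#' (DAPI channel: nucleus discs scattered over the section) with a rim region
#' representing the cortical plate, where two punctate marker channels are
#' placed. A fraction \code{overlapFraction} of marker-B puncta are co-centered
#' with marker-A puncta (drawn per punctum as a Bernoulli trial); the rest are
#' placed away from every A punctum, so the downstream colocalized-area /
#' marker-B-area ratio estimates \code{overlapFraction}.
#'
#' @slot sectionRadius numeric(1). Section disc radius (um).
#' @slot rimWidth numeric(1). Width (um) of the rim annulus that receives the
#'   puncta; must not exceed \code{sectionRadius}.
#' @slot nNuclei integer-like numeric(1). Number of nucleus discs.
#' @slot nucleusRadius numeric(1). Nucleus disc radius (um).
#' @slot nPuncta integer-like numeric(1). Puncta per marker channel.
#' @slot punctaSigma numeric(1). Gaussian punctum SD (um).
#' @slot overlapFraction numeric(1) in [0, 1].
#' @slot pixelSize numeric(1). um per pixel; the default 0.1563257 is the
#'   confocal acquisition scale the quantification assumes.
#' @slot seed integer-like numeric(1). RNG seed.
#'
#' @return \code{ConfocalPhantomParams()} returns a validated object.
#' @examples
#' ConfocalPhantomParams(overlapFraction = 0.5, seed = 7)
#' @export ConfocalPhantomParams
#' @exportClass ConfocalPhantomParams
setClass("ConfocalPhantomParams",
  representation(
    sectionRadius = "numeric", rimWidth = "numeric", nNuclei = "numeric",
    nucleusRadius = "numeric", nPuncta = "numeric", punctaSigma = "numeric",
    overlapFraction = "numeric", pixelSize = "numeric", seed = "numeric"
  ),
  prototype(
    sectionRadius = 250, rimWidth = 50, nNuclei = 300, nucleusRadius = 3,
    nPuncta = 150, punctaSigma = 0.4, overlapFraction = 0.5,
    pixelSize = 0.1563257, seed = 1
  )
)

setValidity("ConfocalPhantomParams", function(object) {
  msg <- character()
  for (s in slotNames(object)) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) {
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    }
  }
  if (length(msg)) return(msg)
  if (object@sectionRadius <= 0) msg <- c(msg, "sectionRadius must be > 0")
  if (object@rimWidth <= 0 || object@rimWidth > object@sectionRadius) {
    msg <- c(msg, "need 0 < rimWidth <= sectionRadius")
  }
  if (object@nNuclei < 0) msg <- c(msg, "nNuclei must be >= 0")
  if (object@nucleusRadius <= 0) msg <- c(msg, "nucleusRadius must be > 0")
  if (object@nPuncta < 0) msg <- c(msg, "nPuncta must be >= 0")
  if (object@punctaSigma <= 0) msg <- c(msg, "punctaSigma must be > 0")
  if (object@overlapFraction < 0 || object@overlapFraction > 1) {
    msg <- c(msg, "overlapFraction must be in [0, 1]")
  }
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (abs(object@seed) >= 2^31) msg <- c(msg, "seed must fit a 32-bit integer")
  if (length(msg)) msg else TRUE
})

#' @rdname ConfocalPhantomParams-class
#' @param sectionRadius,rimWidth,nNuclei,nucleusRadius,nPuncta,punctaSigma,overlapFraction,pixelSize,seed
#'   see the slot documentation.
ConfocalPhantomParams <- function(sectionRadius = 250, rimWidth = 50,
                                  nNuclei = 300, nucleusRadius = 3,
                                  nPuncta = 150, punctaSigma = 0.4,
                                  overlapFraction = 0.5,
                                  pixelSize = 0.1563257, seed = 1) {
  new("ConfocalPhantomParams",
    sectionRadius = sectionRadius, rimWidth = rimWidth, nNuclei = nNuclei,
    nucleusRadius = nucleusRadius, nPuncta = nPuncta,
    punctaSigma = punctaSigma, overlapFraction = overlapFraction,
    pixelSize = pixelSize, seed = seed
  )
}

#' Colocalization and particle-analysis parameters
#'
#' @slot tA,tB numeric(1). Per-channel 8-bit thresholds (0-255); both channels
#'   must meet their threshold for a pixel to enter any mask. Equal thresholds
#'   across all samples of an experiment are the caller's responsibility.
#' @slot rho numeric(1). Mutual-intensity fraction: a pixel is colocalized
#'   when \code{min(IA, IB) / max(IA, IB) >= rho} in addition to both
#'   thresholds. Default 0.10 ("colocalized by at least 10 percent of their
#'   intensities").
#' @slot connectivity numeric(1). 4 or 8; pixel connectivity for particle
#'   labeling.
#' @slot minParticleSize numeric(1). Minimum particle size in pixels.
#' @slot ratioFloor numeric(1). Denominator floor (8-bit counts) below which
#'   pixels are excluded from ratiometric measurement.
#'
#' @return \code{ColocParams()} returns a validated object.
#' @examples
#' ColocParams(tA = 25, tB = 25)
#' @export ColocParams
#' @exportClass ColocParams
setClass("ColocParams",
  representation(
    tA = "numeric", tB = "numeric", rho = "numeric",
    connectivity = "numeric", minParticleSize = "numeric",
    ratioFloor = "numeric"
  ),
  prototype(
    tA = 1, tB = 1, rho = 0.10, connectivity = 8,
    minParticleSize = 1, ratioFloor = 1
  )
)

setValidity("ColocParams", function(object) {
  msg <- character()
  for (s in slotNames(object)) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) {
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    }
  }
  if (length(msg)) return(msg)
  if (object@tA < 0 || object@tA > 255) msg <- c(msg, "tA must be in [0, 255]")
  if (object@tB < 0 || object@tB > 255) msg <- c(msg, "tB must be in [0, 255]")
  if (object@rho <= 0 || object@rho > 1) msg <- c(msg, "rho must be in (0, 1]")
  if (!object@connectivity %in% c(4, 8)) {
    msg <- c(msg, "connectivity must be 4 or 8")
  }
  if (object@minParticleSize < 1) msg <- c(msg, "minParticleSize must be >= 1")
  if (object@ratioFloor < 0) msg <- c(msg, "ratioFloor must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ColocParams-class
#' @param tA,tB,rho,connectivity,minParticleSize,ratioFloor see the slot
#'   documentation.
ColocParams <- function(tA = 1, tB = 1, rho = 0.10, connectivity = 8,
                        minParticleSize = 1, ratioFloor = 1) {
  new("ColocParams",
    tA = tA, tB = tB, rho = rho, connectivity = connectivity,
    minParticleSize = minParticleSize, ratioFloor = ratioFloor
  )
}

# ---------------------------------------------------------------------------
# Data classes
# ---------------------------------------------------------------------------

.locColumns <- c("channel", "x_nm", "y_nm", "z_nm", "frame", "photons")

#' Per-molecule localization table
#'
#' Thin validated container around a data.frame of single-molecule
#' localizations with the canonical columns \code{channel, x_nm, y_nm, z_nm,
#' frame, photons}. Extra columns are retained untouched.
#'
#' @slot records data.frame with the canonical columns.
#'
#' @return \code{LocalizationTable(records)} returns a validated object.
#' @seealso [readLocalizationTable()], [renderLocalizations()]
#' @examples
#' LocalizationTable(data.frame(
#'   channel = "pre", x_nm = 0, y_nm = 0, z_nm = 0, frame = 1L, photons = 500
#' ))
#' @export LocalizationTable
#' @exportClass LocalizationTable
setClass("LocalizationTable", representation(records = "data.frame"))

setValidity("LocalizationTable", function(object) {
  df <- object@records
  missing <- setdiff(.locColumns, names(df))
  if (length(missing)) {
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  msg <- character()
  for (col in c("x_nm", "y_nm", "z_nm", "frame", "photons")) {
    if (!is.numeric(df[[col]])) msg <- c(msg, sprintf("'%s' must be numeric", col))
    else if (anyNA(df[[col]])) msg <- c(msg, sprintf("'%s' contains NA", col))
  }
  if (!(is.character(df$channel) || is.factor(df$channel))) {
    msg <- c(msg, "'channel' must be character or factor")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname LocalizationTable-class
#' @param records data.frame with columns
#'   \code{channel, x_nm, y_nm, z_nm, frame, photons}.
LocalizationTable <- function(records) {
  records$channel <- as.character(records$channel)
  new("LocalizationTable", records = records)
}

#' One-synapse region of interest
#'
#' The unit of the super-resolution analysis: a single synapse given either as
#' a localization subset (preferred) or as a named list of per-channel image
#' stacks, together with the mapping from channel roles (\code{pre},
#' \code{post}, \code{matrix}) to channel labels and the rendering pixel size.
#'
#' @slot localizations A [LocalizationTable-class] (possibly with 0 rows for
#'   the matrix channel) or NULL when image stacks are supplied.
#' @slot stack Named list (\code{pre}, \code{post}, \code{matrix}) of numeric
#'   arrays, each \code{nx x ny} or \code{nx x ny x nplanes}, or NULL.
#' @slot channelRoles Named character: role -> channel label (localization
#'   route only).
#' @slot pixelSize numeric(1), nm per pixel. Default 2 nm, the typical export
#'   scale of reconstructed dSTORM synapse images.
#'
#' @return \code{SynapseROI()} returns a validated object.
#' @examples
#' sim <- simulateSynapse(SynapseSimParams(seed = 3))
#' roi <- SynapseROI(localizations = sim$table)
#' @export SynapseROI
#' @exportClass SynapseROI
setClass("SynapseROI",
  representation(
    localizations = "ANY", stack = "ANY",
    channelRoles = "character", pixelSize = "numeric"
  ),
  prototype(
    localizations = NULL, stack = NULL,
    channelRoles = c(pre = "pre", post = "post", matrix = "matrix"),
    pixelSize = 2
  )
)

setValidity("SynapseROI", function(object) {
  msg <- character()
  hasLoc <- !is.null(object@localizations)
  hasStack <- !is.null(object@stack)
  if (hasLoc == hasStack) {
    return("exactly one of 'localizations' or 'stack' must be supplied")
  }
  if (hasLoc && !is(object@localizations, "LocalizationTable")) {
    msg <- c(msg, "'localizations' must be a LocalizationTable")
  }
  if (hasStack) {
    if (!is.list(object@stack) ||
        !all(c("pre", "post", "matrix") %in% names(object@stack))) {
      msg <- c(msg, "'stack' must be a named list with pre, post, matrix")
    } else {
      for (role in c("pre", "post", "matrix")) {
        a <- object@stack[[role]]
        if (!is.numeric(a) || !(length(dim(a)) %in% c(2L, 3L))) {
          msg <- c(msg, sprintf("stack '%s' must be a 2-D or 3-D numeric array", role))
        }
      }
    }
  }
  roles <- object@channelRoles
  if (!all(c("pre", "post", "matrix") %in% names(roles))) {
    msg <- c(msg, "channelRoles must name pre, post and matrix")
  }
  if (anyDuplicated(roles[c("pre", "post", "matrix")])) {
    msg <- c(msg, "each role must map to a distinct channel")
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) {
    msg <- c(msg, "pixelSize must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SynapseROI-class
#' @param localizations,stack,channelRoles,pixelSize see the slot
#'   documentation.
SynapseROI <- function(localizations = NULL, stack = NULL,
                       channelRoles = c(pre = "pre", post = "post",
                                        matrix = "matrix"),
                       pixelSize = 2) {
  new("SynapseROI",
    localizations = localizations, stack = stack,
    channelRoles = channelRoles, pixelSize = pixelSize
  )
}

.cleftClasses <- c(
  "IN_CLEFT", "NEAR_CLEFT", "PRE_PREFERENTIAL", "POST_PREFERENTIAL", "ABSENT"
)
.compartmentClasses <- c("BOTH", "PRE_ONLY", "POST_ONLY", "NEITHER")

#' Per-synapse measurement
#'
#' Result of [analyzeSynapse()]: per-channel centroids, matrix-to-marker
#' centroid distances, pre-to-post separation, the five-way cleft class, the
#' compartment assignment and the perpendicular intensity profiles.
#'
#' @slot centroids numeric matrix, rows \code{pre, post, matrix}, columns
#'   \code{x, y} (nm). The matrix row is NA when no signal was found.
#' @slot dPre,dPost numeric(1). Matrix-to-marker centroid distances (nm); NA
#'   when the matrix channel has no signal.
#' @slot separation numeric(1). Pre-to-post centroid distance (nm).
#' @slot present logical(1). Outcome of the presence criterion.
#' @slot cleftClass character(1). One of IN_CLEFT, NEAR_CLEFT,
#'   PRE_PREFERENTIAL, POST_PREFERENTIAL, ABSENT.
#' @slot compartmentClass character(1). One of BOTH, PRE_ONLY, POST_ONLY,
#'   NEITHER (NA when absent).
#' @slot profiles list with \code{position_nm} and one numeric vector per
#'   channel role; retained for QC and plotting.
#' @slot ruleOrder character(1). Identifier of the classification precedence
#'   applied, recorded for provenance.
#'
#' @seealso [analyzeSynapse()], [aggregateDistribution()]
#' @exportClass SynapseMeasurement
setClass("SynapseMeasurement",
  representation(
    centroids = "matrix", dPre = "numeric", dPost = "numeric",
    separation = "numeric", present = "logical",
    cleftClass = "character", compartmentClass = "character",
    profiles = "list", ruleOrder = "character"
  )
)

setValidity("SynapseMeasurement", function(object) {
  msg <- character()
  if (!all(c("pre", "post", "matrix") %in% rownames(object@centroids))) {
    msg <- c(msg, "centroids must have rows pre, post, matrix")
  }
  if (!object@cleftClass %in% .cleftClasses) {
    msg <- c(msg, "unknown cleftClass")
  }
  if (!is.na(object@compartmentClass) &&
      !object@compartmentClass %in% .compartmentClasses) {
    msg <- c(msg, "unknown compartmentClass")
  }
  if (isTRUE(object@present) != (object@cleftClass != "ABSENT")) {
    msg <- c(msg, "cleftClass is ABSENT iff the presence criterion failed")
  }
  ok <- function(v) is.na(v) || v >= 0
  if (!ok(object@dPre) || !ok(object@dPost) || !ok(object@separation)) {
    msg <- c(msg, "distances must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth for one simulated synapse
#'
#' Generator-side record of the intended geometry of a simulated synapse. The
#' label is always derivable from the noiseless true geometry by
#' [classifyCleftLocalization()] with default parameters.
#'
#' @slot label character(1). Intended cleft class.
#' @slot trueCentroids numeric matrix, rows \code{pre, post, matrix}, columns
#'   \code{x, y, z} (nm); matrix row NA when absent.
#' @slot dPre,dPost,separation numeric(1). Noiseless distances (nm).
#' @slot params The [SynapseSimParams-class] that produced the synapse.
#'
#' @seealso [simulateSynapse()]
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    label = "character", trueCentroids = "matrix",
    dPre = "numeric", dPost = "numeric", separation = "numeric",
    params = "SynapseSimParams"
  )
)

setValidity("GroundTruth", function(object) {
  if (!object@label %in% .cleftClasses) return("unknown label")
  TRUE
})

#' Gated two-group comparison
#'
#' Result of [compareGroups()]: both samples are first screened with
#' Shapiro-Wilk; when neither rejects normality at \code{alpha} the groups are
#' compared with a two-sided equal-variance Student t-test, otherwise with a
#' two-sided Mann-Whitney rank-sum test.
#'
#' @slot nA,nB integer(1). Group sizes.
#' @slot shapiroPA,shapiroPB numeric(1). Normality p-values (NA for a constant
#'   sample, which is treated as non-normal).
#' @slot test character(1). "t" or "mann-whitney".
#' @slot statistic,pValue numeric(1). Test statistic and two-sided p-value.
#' @slot alpha numeric(1). Gate and test level.
#'
#' @seealso [compareGroups()]
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(
    nA = "integer", nB = "integer",
    shapiroPA = "numeric", shapiroPB = "numeric",
    test = "character", statistic = "numeric", pValue = "numeric",
    alpha = "numeric"
  )
)

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (!object@test %in% c("t", "mann-whitney")) msg <- c(msg, "unknown test")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1)) {
    msg <- c(msg, "pValue must be in [0, 1]")
  }
  bothNormal <- !is.na(object@shapiroPA) && !is.na(object@shapiroPB) &&
    object@shapiroPA > object@alpha && object@shapiroPB > object@alpha
  if (bothNormal != (object@test == "t")) {
    msg <- c(msg, "t-test is chosen iff both groups pass the normality gate")
  }
  if (length(msg)) msg else TRUE
})
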