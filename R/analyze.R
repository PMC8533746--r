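# Per-synapse analysis: the full super-resolution measurement chain.

#' Analyze one synapse ROI
#'
#' Runs the complete per-synapse chain: channel rendering (localization route)
#' or maximum-intensity projection (image route), Gaussian pre-blur,
#' intensity-weighted centroids, presence criterion, cleft geometry,
#' perpendicular intensity profiles, the five-way cleft classification and the
#' compartment assignment. Deterministic for fixed input.
#'
#' The presence criterion guards the \code{ABSENT} class: on the localization
#' route the matrix channel must contribute at least \code{presenceMin}
#' localizations within \code{windowRadius} nm of the cleft midpoint; on the
#' image route the integrated blurred matrix intensity within that window must
#' reach \code{presenceMin}.
#'
#' @param roi a [SynapseROI-class].
#' @param params a [CleftClassParams-class].
#' @param use3d logical; when TRUE (localization route only) the centroid
#'   distances are computed from the 3-D localization means instead of the
#'   2-D projection. Default FALSE: the analysis operates on projections.
#' @return a [SynapseMeasurement-class].
#' @examples
#' sim <- simulateSynapse(presetSimParams("IN_CLEFT", seed = 8))
#' m <- analyzeSynapse(SynapseROI(localizations = sim$table, pixelSize = 5))
#' cleftClass(m)
#' @export
analyzeSynapse <- function(roi, params = CleftClassParams(), use3d = FALSE) {
  stopifnot(is(roi, "SynapseROI"), is(params, "CleftClassParams"))
  validObject(roi)
  validObject(params)
  locRoute <- !is.null(roi@localizations)
  if (use3d && !locRoute) stop("3-D distances require the localization route")

  grids <- projectAndBlur(roi, params)
  pixelSize <- .gridPixelSize(grids$pre, default = roi@pixelSize)

  cenPre <- channelCentroid(grids$pre)
  cenPost <- channelCentroid(grids$post)
  if (anyNA(cenPre) || anyNA(cenPost)) {
    stop("pre/post marker channel has no signal")
  }
  cenMat <- channelCentroid(grids$matrix)
  geo <- cleftGeometry(cenPre, cenPost)

  present <- if (locRoute) {
    df <- locData(roi@localizations)
    mdf <- df[df$channel == roi@channelRoles[["matrix"]], , drop = FALSE]
    if (nrow(mdf)) {
      r2 <- (mdf$x_nm - geo$midpoint[1])^2 + (mdf$y_nm - geo$midpoint[2])^2
      sum(r2 <= params@windowRadius^2) >= params@presenceMin
    } else FALSE
  } else {
    .windowIntensity(grids$matrix, geo$midpoint, params@windowRadius) >=
      params@presenceMin
  }
  present <- present && !anyNA(cenMat)

  if (use3d) {
    df <- locData(roi@localizations)
    m3 <- function(ch) {
      d <- df[df$channel == roi@channelRoles[[ch]], , drop = FALSE]
      c(mean(d$x_nm), mean(d$y_nm), mean(d$z_nm))
    }
    dPre <- if (present) sqrt(sum((m3("matrix") - m3("pre"))^2)) else NA_real_
    dPost <- if (present) sqrt(sum((m3("matrix") - m3("post"))^2)) else NA_real_
  } else {
    dPre <- if (present) sqrt(sum((cenMat - cenPre)^2)) else NA_real_
    dPost <- if (present) sqrt(sum((cenMat - cenPost)^2)) else NA_real_
  }

  cls <- classifyCleftLocalization(
    dPre = if (present) dPre else 0, dPost = if (present) dPost else 0,
    present = present, params = params
  )
  comp <- if (present) {
    classifyCompartment(dPre, dPost, params@thetaNear)
  } else NA_character_

  profiles <- intensityProfiles(grids, geo, width = params@profileWidth,
                                pixelSize = pixelSize)

  cen <- rbind(pre = cenPre, post = cenPost, matrix = cenMat)
  colnames(cen) <- c("x", "y")
  new("SynapseMeasurement",
    centroids = cen, dPre = dPre, dPost = dPost,
    separation = geo$separation, present = present,
    cleftClass = as.character(cls), compartmentClass = comp,
    profiles = profiles, ruleOrder = attr(cls, "ruleOrder")
  )
}

# Integrated intensity within a circular window (pixel centers).
.windowIntensity <- function(grid, center, radius) {
  o <- .gridOrigin(grid)
  s <- .gridPixelSize(grid, default = 1)
  cx <- .pixelCenters(nrow(grid), o[1], s)
  cy <- .pixelCenters(ncol(grid), o[2], s)
  d2 <- outer(cx - center[1], cy - center[2], function(a, b) a^2 + b^2)
  sum(grid[d2 <= radius^2])
}

#' Analyze a batch of synapse ROIs
#'
#' @param rois list of [SynapseROI-class] objects, or the output of
#'   [simulateSynapseBatch()] (in which case each element's \code{table} is
#'   wrapped into an ROI at \code{pixelSize}).
#' @param params a [CleftClassParams-class].
#' @param pixelSize nm per pixel used when wrapping simulated tables.
#' @return data.frame with one row per synapse: distances, separation,
#'   presence, cleft class and compartment class.
#' @examples
#' batch <- simulateSynapseBatch(c("IN_CLEFT", "ABSENT"), baseSeed = 20)
#' analyzeSynapses(batch, pixelSize = 5)
#' @export
analyzeSynapses <- function(rois, params = CleftClassParams(), pixelSize = 2) {
  stopifnot(is.list(rois), length(rois) >= 1)
  rows <- lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    if (!is(r, "SynapseROI")) {
      r <- SynapseROI(localizations = r$table, pixelSize = pixelSize)
    }
    m <- analyzeSynapse(r, params)
    data.frame(
      id = i, d_pre_nm = m@dPre, d_post_nm = m@dPost,
      separation_nm = m@separation, present = m@present,
      cleft_class = m@cleftClass, compartment_class = m@compartmentClass,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
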