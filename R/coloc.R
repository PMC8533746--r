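# Confocal-scale quantification: 8-bit conversion, colocalization mask,
# edge sampling ROIs, DAPI-normalized areas, particle and ratiometric stats.

#' Convert an image to 8-bit
#'
#' Linear map of the display range \code{[min, max]} to \code{[0, 255]},
#' clipped and rounded half-up — the convention under which the confocal
#' quantification operates on every channel. Conversion is idempotent on an
#' already 8-bit channel with range \code{c(0, 255)}.
#'
#' @param image numeric matrix or \code{nx x ny x nchannel} array.
#' @param range display range: numeric(2) applied to every channel, or a list
#'   of numeric(2) per channel. NULL uses each channel's own data range.
#' @return numeric matrix/array of integers in 0-255 with attribute
#'   \code{displayRange} (and \code{rounding = "half-up"}).
#' @examples
#' convert8bit(matrix(c(0, 32768, 65535), 1, 3), range = c(0, 65535))
#' @export
convert8bit <- function(image, range = NULL) {
  if (is.matrix(image)) {
    ch <- list(image)
  } else if (length(dim(image)) == 3) {
    ch <- lapply(seq_len(dim(image)[3]), function(k) image[, , k])
  } else stop("'image' must be a matrix or 3-D array")

  ranges <- if (is.null(range)) {
    lapply(ch, range)
  } else if (is.numeric(range) && length(range) == 2) {
    rep(list(range), length(ch))
  } else if (is.list(range) && length(range) == length(ch)) {
    range
  } else stop("'range' must be numeric(2), a per-channel list, or NULL")

  conv <- mapply(function(m, r) {
    if (!(r[2] > r[1])) stop("degenerate display range")
    v <- (m - r[1]) * 255 / (r[2] - r[1])
    matrix(floor(pmin(pmax(v, 0), 255) + 0.5), nrow(m), ncol(m))
  }, ch, ranges, SIMPLIFY = FALSE)

  out <- if (is.matrix(image)) conv[[1]] else {
    a <- array(unlist(conv), dim(image), dimnames = dimnames(image))
    a
  }
  attr(out, "displayRange") <- if (length(ranges) == 1) ranges[[1]] else ranges
  attr(out, "rounding") <- "half-up"
  attr(out, "pixelSize") <- attr(image, "pixelSize")
  out
}

#' Mutual-intensity colocalization mask
#'
#' A pixel is colocalized when both channels reach their thresholds and the
#' channels share at least the fraction \code{rho} of their intensities,
#' implemented as the pixelwise ratio \code{min(IA, IB) / max(IA, IB) >= rho}
#' (default 0.10 — the "colocalized by at least 10 percent of their
#' intensities" criterion of the classic ImageJ colocalization output). The
#' criterion is symmetric in the two channels.
#'
#' @param chA,chB numeric matrices of equal shape (8-bit intensities).
#' @param params a [ColocParams-class] supplying \code{tA}, \code{tB},
#'   \code{rho}.
#' @return logical matrix; attribute \code{criterion} records the rule.
#' @examples
#' a <- matrix(200, 2, 2); b <- matrix(c(10, 25, 100, 200), 2, 2)
#' colocMask(a, b, ColocParams(tA = 1, tB = 1))
#' @export
colocMask <- function(chA, chB, params = ColocParams()) {
  stopifnot(is(params, "ColocParams"))
  if (!identical(dim(chA), dim(chB))) stop("channel shapes differ")
  lo <- pmin(chA, chB)
  hi <- pmax(chA, chB)
  ratio <- ifelse(hi > 0, lo / hi, 0)
  mask <- chA >= params@tA & chB >= params@tB & ratio >= params@rho
  attr(mask, "criterion") <- sprintf(
    "IA >= %g & IB >= %g & min/max >= %g", params@tA, params@tB, params@rho
  )
  mask
}

#' Circular sampling regions along the section edge
#'
#' Places up to \code{n} non-overlapping circular sampling regions of the
#' given diameter along the edge of the tissue section (the cortical-plate
#' location): ROI centers are inset from the section boundary by one ROI
#' radius and spaced at equal boundary angles around the section centroid. The
#' seed controls only the angular start; fixed seed gives identical centers.
#'
#' @param dapiMask logical (or 0/1 numeric) matrix: tissue section footprint
#'   derived from the DAPI channel.
#' @param n requested number of regions (default 10).
#' @param diameter ROI diameter in um (default 100).
#' @param pixelSize um per pixel of the mask.
#' @param seed optional integer controlling the angular start.
#' @return data.frame with columns \code{index, cx_um, cy_um, diameter_um}.
#'   When fewer than \code{n} regions fit, the shortfall is warned about and
#'   reflected in the row count (possibly zero rows).
#' @examples
#' px <- 1
#' m <- outer(1:300, 1:300, function(i, j)
#'   (i - 150)^2 + (j - 150)^2 <= 140^2)
#' rois <- sampleEdgeROIs(m, n = 6, diameter = 60, pixelSize = px, seed = 1)
#' @export
sampleEdgeROIs <- function(dapiMask, n = 10, diameter = 100, pixelSize,
                           seed = NULL) {
  if (diameter <= 0) stop("'diameter' must be > 0")
  .assertScalarNumber(pixelSize, "pixelSize", positive = TRUE)
  mask <- dapiMask > 0
  if (!any(mask)) stop("empty section mask")
  rad <- diameter / 2

  idx <- which(mask, arr.ind = TRUE)
  cx <- (idx[, 1] - 0.5) * pixelSize
  cy <- (idx[, 2] - 0.5) * pixelSize
  cen <- c(mean(cx), mean(cy))

  start <- .withSeed(seed, stats::runif(1, 0, 2 * pi / n))
  angles <- start + 2 * pi * (seq_len(n) - 1) / n

  # boundary distance per angle: furthest mask pixel within a narrow angular
  # sector around each direction
  theta <- atan2(cy - cen[2], cx - cen[1])
  r <- sqrt((cx - cen[1])^2 + (cy - cen[2])^2)
  halfSector <- pi / max(n, 36)
  centers <- t(vapply(angles, function(a) {
    d <- atan2(sin(theta - a), cos(theta - a))
    sel <- abs(d) <= halfSector
    if (!any(sel)) return(c(NA_real_, NA_real_))
    rb <- max(r[sel])
    cen + (rb - rad) * c(cos(a), sin(a))
  }, numeric(2)))

  insideMask <- function(p) {
    # ROI must sit inside the section: test center and a 16-point ring
    a <- seq(0, 2 * pi, length.out = 17)[-17]
    pts <- cbind(p[1] + 0.98 * rad * cos(a), p[2] + 0.98 * rad * sin(a))
    pts <- rbind(pts, p)
    i <- pmin(pmax(ceiling(pts[, 1] / pixelSize), 1), nrow(mask))
    j <- pmin(pmax(ceiling(pts[, 2] / pixelSize), 1), ncol(mask))
    all(mask[cbind(i, j)]) &&
      all(pts[, 1] >= 0 & pts[, 1] <= nrow(mask) * pixelSize &
          pts[, 2] >= 0 & pts[, 2] <= ncol(mask) * pixelSize)
  }
  ok <- apply(centers, 1, function(p) !anyNA(p) && insideMask(p))

  # enforce pairwise non-overlap among the survivors
  keep <- which(ok)
  if (length(keep) > 1) {
    sel <- keep[1]
    for (k in keep[-1]) {
      d2 <- (centers[sel, 1] - centers[k, 1])^2 +
        (centers[sel, 2] - centers[k, 2])^2
      if (all(d2 >= diameter^2)) sel <- c(sel, k)
    }
    keep <- sel
  }
  if (length(keep) < n) {
    warning(sprintf("placed %d of %d requested edge ROIs", length(keep), n))
  }
  data.frame(
    index = seq_along(keep),
    cx_um = centers[keep, 1, drop = TRUE], cy_um = centers[keep, 2, drop = TRUE],
    diameter_um = rep(diameter, length(keep))
  )
}

#' Mask area inside a sampling region, normalized to DAPI
#'
#' Areas are pixel counts times the squared pixel size; the normalized ratio
#' is the mask area divided by the DAPI area in the same region. A region with
#' zero DAPI area yields an NA ratio flagged in the result, not an error.
#'
#' @param mask,dapiMask logical matrices of equal shape.
#' @param roi NULL (whole image) or a circular region: one row of
#'   [sampleEdgeROIs()] output or numeric \code{c(cx_um, cy_um, diameter_um)}.
#' @param pixelSize um per pixel.
#' @return list with \code{area_um2}, \code{dapi_area_um2}, \code{ratio} and
#'   logical \code{flagged}.
#' @examples
#' m <- matrix(FALSE, 10, 10); m[1:2, 1:5] <- TRUE
#' d <- matrix(TRUE, 10, 10); d[6:10, ] <- FALSE
#' normalizedArea(m, d, pixelSize = 0.1563257)
#' @export
normalizedArea <- function(mask, dapiMask, roi = NULL, pixelSize) {
  if (!identical(dim(mask), dim(dapiMask))) stop("mask shapes differ")
  .assertScalarNumber(pixelSize, "pixelSize", positive = TRUE)
  sel <- .roiSelector(dim(mask), roi, pixelSize)
  a <- sum(mask[sel] > 0) * pixelSize^2
  d <- sum(dapiMask[sel] > 0) * pixelSize^2
  flagged <- d == 0
  if (flagged) warning("zero DAPI area in ROI; ratio is NA")
  list(
    area_um2 = a, dapi_area_um2 = d,
    ratio = if (flagged) NA_real_ else a / d,
    flagged = flagged
  )
}

.roiSelector <- function(dims, roi, pixelSize) {
  if (is.null(roi)) return(matrix(TRUE, dims[1], dims[2]))
  if (is.data.frame(roi)) roi <- c(roi$cx_um[1], roi$cy_um[1], roi$diameter_um[1])
  cx <- .pixelCenters(dims[1], 0, pixelSize)
  cy <- .pixelCenters(dims[2], 0, pixelSize)
  outer(cx - roi[1], cy - roi[2], function(a, b) a^2 + b^2) <= (roi[3] / 2)^2
}

#' Label connected particles in a binary mask
#'
#' Connected-component labeling at 4- or 8-connectivity, computed as the
#' components of the pixel adjacency graph.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix: 0 background, 1..k particle labels.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, 2)
#' max(labelParticles(m, 8))  # diagonal pixels join at 8-connectivity
#' max(labelParticles(m, 4))  # but not at 4-connectivity
#' @export
labelParticles <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  fg <- which(m)
  lab <- matrix(0L, nr, nc)
  if (!length(fg)) return(lab)

  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  ij <- arrayInd(fg, c(nr, nc))
  for (sft in shifts) {
    i2 <- ij[, 1] + sft[1]; j2 <- ij[, 2] + sft[2]
    ok <- i2 >= 1L & i2 <= nr & j2 >= 1L & j2 <= nc
    if (!any(ok)) next
    nb <- id[cbind(i2[ok], j2[ok])]
    has <- nb > 0L
    if (any(has)) {
      edges[[length(edges) + 1L]] <- cbind(id[fg][ok][has], nb[has])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(e))
  }
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

#' Particle count and sizes
#'
#' Connected components of a binary mask at the configured connectivity;
#' components smaller than \code{minParticleSize} pixels are dropped. Sizes
#' are reported in square um.
#'
#' @param mask logical matrix.
#' @param params a [ColocParams-class] (connectivity, minimum size).
#' @param pixelSize um per pixel.
#' @return list with \code{count}, \code{sizes_um2}, \code{sizes_px} and the
#'   filtered label matrix \code{labels}.
#' @examples
#' m <- matrix(0, 5, 5); m[1:2, 1] <- 1; m[4:5, 4] <- 1
#' particleStats(m, pixelSize = 0.1563257)$count
#' @export
particleStats <- function(mask, params = ColocParams(), pixelSize) {
  stopifnot(is(params, "ColocParams"))
  .assertScalarNumber(pixelSize, "pixelSize", positive = TRUE)
  lab <- labelParticles(mask, params@connectivity)
  if (!any(lab > 0)) {
    return(list(count = 0L, sizes_um2 = numeric(), sizes_px = integer(),
                labels = lab))
  }
  sz <- tabulate(lab[lab > 0])
  keep <- which(sz >= params@minParticleSize)
  relab <- integer(length(sz))
  relab[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  list(
    count = length(keep),
    sizes_um2 = sz[keep] * pixelSize^2,
    sizes_px = as.integer(sz[keep]),
    labels = out
  )
}

#' Ratiometric measurement within particles
#'
#' Divides the numerator channel by the denominator channel pixelwise (the
#' activity-ratio image, e.g. GTP-bound over total protein) wherever the
#' denominator reaches \code{ratioFloor}, then averages the ratio within each
#' particle of the source mask (e.g. the pre-synaptic marker area). Pixels
#' below the floor are excluded and counted, never divided; a particle whose
#' pixels are all excluded gets an NA mean and is flagged.
#'
#' @param numerator,denominator numeric matrices of equal shape.
#' @param sourceMask logical matrix defining the particles to measure.
#' @param params a [ColocParams-class] (connectivity, minimum size, floor).
#' @param pixelSize um per pixel.
#' @return list with \code{ratioImage} (NA where excluded), \code{particles}
#'   (data.frame: label, size_px, size_um2, mean_ratio, n_excluded, flagged)
#'   and \code{excludedPixelCount} within the source mask.
#' @examples
#' num <- matrix(4, 3, 3); den <- matrix(2, 3, 3)
#' src <- matrix(TRUE, 3, 3)
#' ratiometricParticles(num, den, src, pixelSize = 0.1563257)$particles
#' @export
ratiometricParticles <- function(numerator, denominator, sourceMask,
                                 params = ColocParams(), pixelSize) {
  stopifnot(is(params, "ColocParams"))
  if (!identical(dim(numerator), dim(denominator)) ||
      !identical(dim(numerator), dim(sourceMask))) {
    stop("image shapes differ")
  }
  ok <- denominator >= params@ratioFloor
  ratio <- matrix(NA_real_, nrow(numerator), ncol(numerator))
  ratio[ok] <- numerator[ok] / denominator[ok]

  ps <- particleStats(sourceMask, params, pixelSize)
  rows <- lapply(seq_len(ps$count), function(k) {
    px <- ps$labels == k
    vals <- ratio[px]
    nExcl <- sum(is.na(vals))
    data.frame(
      label = k, size_px = sum(px), size_um2 = sum(px) * pixelSize^2,
      mean_ratio = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE),
      n_excluded = nExcl, flagged = all(is.na(vals))
    )
  })
  particles <- if (length(rows)) do.call(rbind, rows) else data.frame(
    label = integer(), size_px = integer(), size_um2 = numeric(),
    mean_ratio = numeric(), n_excluded = integer(), flagged = logical()
  )
  list(
    ratioImage = ratio,
    particles = particles,
    excludedPixelCount = sum(!ok & sourceMask > 0)
  )
}

#' Quantify a three-channel section image
#'
#' End-to-end confocal quantification of one 8-bit section image (channels
#' \code{dapi}, \code{markerA}, \code{markerB}): per-channel threshold masks,
#' the mutual-intensity colocalization mask, edge sampling regions from the
#' DAPI footprint, per-region areas normalized to DAPI, and particle
#' statistics of the colocalized mask per region.
#'
#' @param image integer array \code{nx x ny x 3} with dimnames
#'   \code{dapi, markerA, markerB} (e.g. from [simulateConfocalSection()] or
#'   [readImageStack()]).
#' @param params a [ColocParams-class].
#' @param dapiThreshold 8-bit threshold defining the tissue footprint.
#' @param nRois,roiDiameter edge sampling design (defaults 10 regions of
#'   100 um).
#' @param pixelSize um per pixel; defaults to the image's \code{pixelSize}
#'   attribute.
#' @param seed passed to [sampleEdgeROIs()].
#' @return list with \code{rois} (the sampling regions), \code{perRoi}
#'   (data.frame: areas and DAPI-normalized ratios per region, particle count
#'   and mean particle size of the colocalized mask) and the three masks.
#' @examples
#' ph <- simulateConfocalSection(ConfocalPhantomParams(
#'   sectionRadius = 25, rimWidth = 10, nPuncta = 20, seed = 5
#' ))
#' q <- quantifySection(ph$image, ColocParams(tA = 25, tB = 25),
#'                      nRois = 4, roiDiameter = 20, seed = 1)
#' @export
quantifySection <- function(image, params = ColocParams(), dapiThreshold = 1,
                            nRois = 10, roiDiameter = 100, pixelSize = NULL,
                            seed = NULL) {
  stopifnot(length(dim(image)) == 3)
  if (is.null(pixelSize)) pixelSize <- attr(image, "pixelSize")
  .assertScalarNumber(pixelSize, "pixelSize", positive = TRUE)
  chn <- dimnames(image)[[3]]
  pick <- function(role) {
    k <- if (!is.null(chn) && role %in% chn) role else match(role, c("dapi", "markerA", "markerB"))
    image[, , k]
  }
  dapi <- pick("dapi"); chA <- pick("markerA"); chB <- pick("markerB")

  dapiMask <- dapi >= dapiThreshold
  maskA <- chA >= params@tA
  maskB <- chB >= params@tB
  cmask <- colocMask(chA, chB, params)

  rois <- sampleEdgeROIs(dapiMask, n = nRois, diameter = roiDiameter,
                         pixelSize = pixelSize, seed = seed)
  perRoi <- do.call(rbind, lapply(seq_len(nrow(rois)), function(i) {
    roi <- rois[i, ]
    aA <- normalizedArea(maskA, dapiMask, roi, pixelSize)
    aB <- normalizedArea(maskB, dapiMask, roi, pixelSize)
    aC <- normalizedArea(cmask, dapiMask, roi, pixelSize)
    sel <- .roiSelector(dim(cmask), roi, pixelSize)
    ps <- particleStats(cmask & sel, params, pixelSize)
    data.frame(
      roi = i,
      area_A = aA$area_um2, area_B = aB$area_um2, area_coloc = aC$area_um2,
      area_dapi = aA$dapi_area_um2,
      ratio_A = aA$ratio, ratio_B = aB$ratio, ratio_coloc = aC$ratio,
      particle_count = ps$count,
      mean_particle_size = if (ps$count) mean(ps$sizes_um2) else NA_real_
    )
  }))
  list(rois = rois, perRoi = perRoi,
       masks = list(dapi = dapiMask, A = maskA, B = maskB, coloc = cmask))
}
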