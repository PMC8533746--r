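# Centroids, cleft geometry and perpendicular intensity profiles.

#' Intensity-weighted channel centroid
#'
#' The operative quantity of the super-resolution analysis: the centroid of a
#' channel's signal in continuous nm coordinates. For an intensity grid this
#' is the intensity-weighted mean of the pixel centers; for a localization
#' table it is the unweighted mean of the localization coordinates.
#'
#' A grid with zero total intensity (or an empty localization selection) is a
#' distinct "no signal" outcome feeding the presence criterion: the method
#' returns \code{c(NA, NA)} rather than throwing.
#'
#' @param x numeric matrix (grid route) or [LocalizationTable-class].
#' @param ... method arguments: \code{pixelSize} and \code{origin} for grids
#'   (defaulting to the grid's attributes), \code{channel} for tables.
#' @return named numeric \code{c(x =, y =)} in nm, or NAs when there is no
#'   signal.
#' @examples
#' g <- matrix(0, 4, 4); g[2, 3] <- 2
#' channelCentroid(g, pixelSize = 10)  # center of pixel (2, 3)
#' @export
setGeneric("channelCentroid", function(x, ...) {
  standardGeneric("channelCentroid")
})

#' @rdname channelCentroid
#' @param pixelSize nm per pixel (default: the grid's \code{pixelSize}
#'   attribute, else 1).
#' @param origin nm coordinates of the grid's low corner (default: the grid's
#'   \code{origin} attribute, else \code{c(0, 0)}).
#' @export
setMethod("channelCentroid", "matrix", function(x, pixelSize = NULL,
                                                origin = NULL, ...) {
  if (is.null(pixelSize)) pixelSize <- .gridPixelSize(x, default = 1)
  if (is.null(origin)) origin <- .gridOrigin(x)
  if (any(x < 0)) stop("negative intensities")
  tot <- sum(x)
  if (tot == 0) return(c(x = NA_real_, y = NA_real_))
  cx <- .pixelCenters(nrow(x), origin[1], pixelSize)
  cy <- .pixelCenters(ncol(x), origin[2], pixelSize)
  c(
    x = sum(rowSums(x) * cx) / tot,
    y = sum(colSums(x) * cy) / tot
  )
})

#' @rdname channelCentroid
#' @param channel optional channel label to select.
#' @export
setMethod("channelCentroid", "LocalizationTable", function(x, channel = NULL,
                                                           ...) {
  df <- locData(x)
  if (!is.null(channel)) df <- df[df$channel == channel, , drop = FALSE]
  if (nrow(df) == 0) return(c(x = NA_real_, y = NA_real_))
  c(x = mean(df$x_nm), y = mean(df$y_nm))
})

#' Cleft geometry from the two marker centroids
#'
#' The synaptic cleft is operationalized as the region between the pre- and
#' post-synaptic marker centroids: the cleft axis points from pre toward post,
#' the midpoint is their mean, and the separation is the Euclidean distance.
#'
#' @param preCentroid,postCentroid numeric(2), nm.
#' @return list with \code{axis} (unit vector), \code{midpoint} (nm),
#'   \code{separation} (nm).
#' @examples
#' cleftGeometry(c(0, 0), c(30, 40))$separation  # 50
#' @export
cleftGeometry <- function(preCentroid, postCentroid) {
  pre <- as.numeric(preCentroid)[1:2]
  post <- as.numeric(postCentroid)[1:2]
  if (anyNA(pre) || anyNA(post)) stop("marker centroid is undefined")
  d <- post - pre
  sep <- sqrt(sum(d^2))
  if (sep == 0) stop("pre and post centroids coincide")
  list(axis = d / sep, midpoint = (pre + post) / 2, separation = sep)
}

#' Intensity profiles perpendicular to the synaptic cleft
#'
#' For every channel grid, averages the intensity over a strip of
#' \code{width} pixels perpendicular to the cleft axis, sampled along the axis
#' at one-pixel steps from \code{margin} nm before the pre centroid to
#' \code{margin} nm past the post centroid. This reproduces the line-profile
#' view of the synapse used to visualize where each molecule peaks relative to
#' the cleft; classification itself uses the centroids.
#'
#' @param grids named list of 2-D grids as returned by [projectAndBlur()]; all
#'   must share shape, origin and pixel size.
#' @param geometry list from [cleftGeometry()].
#' @param width strip width in pixels (>= 1); samples are taken at the
#'   \code{width} integer pixel offsets centered on the axis.
#' @param pixelSize,origin grid geometry (defaults: attributes of the first
#'   grid).
#' @param margin nm of profile extension beyond each centroid (default 100).
#' @return list with \code{position_nm} (signed axial position, 0 at the pre
#'   centroid) and one numeric profile per channel.
#' @examples
#' g <- matrix(1, 8, 8)
#' geo <- cleftGeometry(c(20, 40), c(60, 40))
#' p <- intensityProfiles(list(pre = g), geo, width = 3, pixelSize = 10,
#'                        margin = 0)
#' @export
intensityProfiles <- function(grids, geometry, width = 5, pixelSize = NULL,
                              origin = NULL, margin = 100) {
  stopifnot(is.list(grids), length(grids) >= 1)
  if (width < 1) stop("'width' must be >= 1 px")
  g1 <- grids[[1]]
  if (is.null(pixelSize)) pixelSize <- .gridPixelSize(g1, default = 1)
  if (is.null(origin)) origin <- .gridOrigin(g1)

  axis <- geometry$axis
  perp <- c(-axis[2], axis[1])
  pre <- geometry$midpoint - geometry$separation / 2 * axis
  t <- seq(-margin, geometry$separation + margin, by = pixelSize)
  offs <- (seq_len(width) - (width + 1) / 2) * pixelSize

  # bail out when the inter-centroid segment leaves the field of view
  lim <- function(p) {
    u <- (p[1] - origin[1]) / pixelSize
    v <- (p[2] - origin[2]) / pixelSize
    u >= 0 && u <= nrow(g1) && v >= 0 && v <= ncol(g1)
  }
  if (!lim(pre) || !lim(pre + geometry$separation * axis)) {
    stop("cleft axis lies outside the image bounds")
  }

  profiles <- lapply(grids, function(g) {
    vapply(t, function(ti) {
      p <- pre + ti * axis
      mean(vapply(offs, function(o) {
        q <- p + o * perp
        .bilinear(g, q[1], q[2], origin, pixelSize)
      }, numeric(1)))
    }, numeric(1))
  })
  c(list(position_nm = t), profiles)
}

# Bilinear interpolation at continuous nm coordinates; border pixels are
# replicated outside the grid of pixel centers.
.bilinear <- function(g, x, y, origin, pixelSize) {
  u <- (x - origin[1]) / pixelSize + 0.5  # pixel-center units
  v <- (y - origin[2]) / pixelSize + 0.5
  u <- min(max(u, 1), nrow(g))
  v <- min(max(v, 1), ncol(g))
  i0 <- floor(u); j0 <- floor(v)
  i1 <- min(i0 + 1, nrow(g)); j1 <- min(j0 + 1, ncol(g))
  fu <- u - i0; fv <- v - j0
  (1 - fu) * (1 - fv) * g[i0, j0] + fu * (1 - fv) * g[i1, j0] +
    (1 - fu) * fv * g[i0, j1] + fu * fv * g[i1, j1]
}
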