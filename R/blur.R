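# Maximum-intensity projection and Gaussian pre-blur.

#' Gaussian blur of a 2-D intensity grid
#'
#' Separable convolution with a sampled Gaussian kernel. The \code{radius}
#' argument is the standard deviation of the Gaussian in pixels (the ImageJ
#' Gaussian Blur convention); the kernel is truncated at 4 radii and
#' renormalized, and the image is zero-padded at the borders.
#'
#' @param img numeric matrix.
#' @param radius Gaussian standard deviation in pixels; 0 returns the input
#'   unchanged.
#' @return numeric matrix of the same shape; \code{origin}/\code{pixelSize}
#'   attributes of the input are preserved.
#' @examples
#' imp <- matrix(0, 9, 9); imp[5, 5] <- 1
#' blurred <- gaussianBlur(imp, radius = 2)
#' sum(blurred)  # ~1: blur conserves total intensity away from borders
#' @export
gaussianBlur <- function(img, radius) {
  if (!is.matrix(img) || !is.numeric(img)) stop("'img' must be a numeric matrix")
  .assertScalarNumber(radius, "radius")
  if (radius < 0) stop("'radius' must be >= 0")
  out <- if (radius == 0) img else {
    k <- .gaussianKernel1d(radius)
    .convSeparable(img, k)
  }
  attr(out, "origin") <- attr(img, "origin")
  attr(out, "pixelSize") <- attr(img, "pixelSize")
  out
}

# 1-D sampled Gaussian, truncated at 4*sigma, normalized to sum 1.
.gaussianKernel1d <- function(sigma) {
  h <- ceiling(4 * sigma)
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 2-D convolution with zero padding, via stats::filter (C speed).
.convSeparable <- function(img, k) {
  h <- (length(k) - 1L) / 2L
  padConv <- function(m) {
    # filter() runs down the columns; pad with h zero rows each side so the
    # NA fringe falls entirely in the padding.
    pad <- matrix(0, h, ncol(m))
    p <- rbind(pad, m, pad)
    f <- stats::filter(p, k, method = "convolution", sides = 2)
    matrix(f[(h + 1L):(h + nrow(m)), ], nrow(m), ncol(m))
  }
  t(padConv(t(padConv(img))))
}

#' Maximum-intensity projection of an image stack
#'
#' Element-wise maximum across the planes of a 3-D array. A 2-D matrix is
#' returned unchanged (a single-plane stack is its own projection).
#'
#' @param stack numeric matrix or 3-D array (\code{nx x ny x nplanes}).
#' @return numeric matrix.
#' @examples
#' a <- array(c(1, 5, 2, 0), c(1, 2, 2))
#' maxProject(a)
#' @export
maxProject <- function(stack) {
  if (is.matrix(stack)) return(stack)
  d <- dim(stack)
  if (length(d) != 3L) stop("'stack' must be a matrix or 3-D array")
  if (d[3] < 1L) stop("empty stack")
  out <- stack[, , 1L, drop = TRUE]
  if (d[3] > 1L) for (p in 2L:d[3]) out <- pmax(out, stack[, , p])
  matrix(out, d[1], d[2])
}

#' Project and pre-blur the channels of a synapse ROI
#'
#' Applies the two preprocessing steps of the super-resolution analysis to
#' every channel: maximum-intensity projection across planes, then Gaussian
#' blur of radius \code{blurRadius(params)} pixels. The blur spreads the
#' weight of single bright localizations so the subsequent centroid is not
#' dominated by one link.
#'
#' @param roi a [SynapseROI-class] or a named list with elements \code{pre},
#'   \code{post}, \code{matrix}, each a numeric matrix or 3-D array. For a
#'   localization-route ROI the channels are first rendered with
#'   [renderLocalizations()] over a common field of view.
#' @param params a [CleftClassParams-class]; only \code{blurRadius} is used
#'   here.
#' @return named list of three 2-D grids (\code{pre}, \code{post},
#'   \code{matrix}) carrying \code{origin} and \code{pixelSize} attributes.
#' @examples
#' sim <- simulateSynapse(SynapseSimParams(seed = 2))
#' grids <- projectAndBlur(SynapseROI(localizations = sim$table),
#'                         CleftClassParams())
#' @export
projectAndBlur <- function(roi, params = CleftClassParams()) {
  stopifnot(is(params, "CleftClassParams"))
  stacks <- if (is(roi, "SynapseROI")) .roiChannelStacks(roi) else roi
  if (!is.list(stacks) || !all(c("pre", "post", "matrix") %in% names(stacks))) {
    stop("'roi' must be a SynapseROI or a named list with pre, post, matrix")
  }
  lapply(stacks[c("pre", "post", "matrix")], function(s) {
    g <- maxProject(if (is.matrix(s)) s else s)
    g2 <- gaussianBlur(g, params@blurRadius)
    attr(g2, "origin") <- attr(s, "origin")
    attr(g2, "pixelSize") <- attr(s, "pixelSize")
    g2
  })
}

# Materialize the per-role channel grids of a SynapseROI. Localization-route
# ROIs are rendered over a common field covering every channel plus a margin
# of 8 px (two blur truncation half-widths at the default radius).
.roiChannelStacks <- function(roi, marginPx = 8) {
  if (!is.null(roi@stack)) return(roi@stack)
  df <- locData(roi@localizations)
  s <- roi@pixelSize
  roles <- roi@channelRoles[c("pre", "post", "matrix")]
  sel <- df$channel %in% roles
  if (!any(df$channel %in% roles[c("pre", "post")])) {
    stop("missing pre/post channel in localization table")
  }
  use <- df[sel, , drop = FALSE]
  margin <- marginPx * s
  xlim <- range(use$x_nm) + c(-margin, margin)
  ylim <- range(use$y_nm) + c(-margin, margin)
  out <- lapply(roles, function(ch) {
    renderLocalizations(roi@localizations, pixelSize = s, channel = ch,
                        xlim = xlim, ylim = ylim, quiet = TRUE)
  })
  names(out) <- names(roles)
  out
}
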