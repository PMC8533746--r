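# Synthetic confocal spheroid sections.

#' Simulate a confocal spheroid section phantom
#'
#' Builds a three-channel 8-bit phantom of a cortical-spheroid cryosection:
#' a DAPI channel of nucleus discs scattered over a circular tissue section,
#' and two punctate marker channels confined to the rim annulus (the cortical
#' plate, where synapse quantification is performed). Puncta are isotropic
#' 2-D Gaussian spots of equal amplitude. A per-punctum Bernoulli draw with
#' probability \code{overlapFraction} co-centers each marker-B punctum on its
#' paired marker-A punctum; non-overlapped puncta keep a minimum separation of
#' six punctum SDs from every other punctum center, so the downstream
#' colocalized-area / marker-B-area ratio estimates \code{overlapFraction}.
#'
#' @param params a [ConfocalPhantomParams-class].
#' @return list with \code{image} (integer array \code{nx x ny x 3}, channels
#'   \code{dapi}, \code{markerA}, \code{markerB}, values 0-255, attribute
#'   \code{pixelSize} in um/px) and \code{truth} (data.frame of punctum
#'   centers in um with the per-punctum \code{overlapped} flag; nuclei rows
#'   carry channel \code{"dapi"}).
#' @examples
#' ph <- simulateConfocalSection(ConfocalPhantomParams(
#'   sectionRadius = 20, rimWidth = 8, nNuclei = 5, nPuncta = 10, seed = 3
#' ))
#' dim(ph$image)
#' @export
simulateConfocalSection <- function(params) {
  stopifnot(is(params, "ConfocalPhantomParams"))
  validObject(params)
  .withSeed(params@seed, {
    s <- params@pixelSize
    margin <- max(2, 4 * params@punctaSigma)
    side <- 2 * (params@sectionRadius + margin)
    n <- ceiling(side / s)
    centerUm <- c(n, n) / 2 * s

    cx <- .pixelCenters(n, 0, s)
    dx <- cx - centerUm[1]
    dy <- cx - centerUm[2]
    r2 <- outer(dx, dy, function(a, b) a^2 + b^2)

    # faint tissue disc (so the section footprint is derivable from the DAPI
    # channel) plus bright nucleus discs
    dapi <- matrix(0, n, n)
    dapi[r2 <= params@sectionRadius^2] <- 30
    nucleiXY <- .sampleInDisc(params@nNuclei,
                              params@sectionRadius - params@nucleusRadius)
    hN <- ceiling(params@nucleusRadius / s) + 1L
    for (i in seq_len(nrow(nucleiXY))) {
      ci <- nucleiXY[i, ] + centerUm
      i0 <- max(1L, floor(ci[1] / s - hN)); i1 <- min(n, ceiling(ci[1] / s + hN))
      j0 <- max(1L, floor(ci[2] / s - hN)); j1 <- min(n, ceiling(ci[2] / s + hN))
      d2 <- outer(cx[i0:i1] - ci[1], cx[j0:j1] - ci[2],
                  function(a, b) a^2 + b^2)
      blk <- dapi[i0:i1, j0:j1]
      blk[d2 <= params@nucleusRadius^2] <- 200
      dapi[i0:i1, j0:j1] <- blk
    }

    dMin <- 6 * params@punctaSigma
    rim <- c(params@sectionRadius - params@rimWidth, params@sectionRadius)
    centersA <- .sampleInAnnulus(params@nPuncta, rim, dMin,
                                 existing = matrix(numeric(), 0, 2))
    overlapped <- stats::runif(params@nPuncta) < params@overlapFraction
    centersB <- matrix(NA_real_, params@nPuncta, 2)
    centersB[overlapped, ] <- centersA[overlapped, , drop = FALSE]
    nFree <- sum(!overlapped)
    if (nFree > 0) {
      centersB[!overlapped, ] <- .sampleInAnnulus(
        nFree, rim, dMin,
        existing = rbind(centersA, centersB[overlapped, , drop = FALSE])
      )
    }

    amp <- 200
    markerA <- .paintPuncta(n, s, centersA + rep(centerUm, each = params@nPuncta),
                            params@punctaSigma, amp)
    markerB <- .paintPuncta(n, s, centersB + rep(centerUm, each = params@nPuncta),
                            params@punctaSigma, amp)

    img <- array(0L, c(n, n, 3), dimnames = list(NULL, NULL,
                                                 c("dapi", "markerA", "markerB")))
    img[, , "dapi"] <- as.integer(pmin(round(dapi), 255))
    img[, , "markerA"] <- as.integer(pmin(round(markerA), 255))
    img[, , "markerB"] <- as.integer(pmin(round(markerB), 255))
    attr(img, "pixelSize") <- s

    truth <- rbind(
      if (nrow(nucleiXY)) data.frame(
        channel = "dapi", index = seq_len(nrow(nucleiXY)),
        x_um = nucleiXY[, 1] + centerUm[1], y_um = nucleiXY[, 2] + centerUm[2],
        overlapped = NA
      ),
      if (params@nPuncta > 0) data.frame(
        channel = "markerA", index = seq_len(params@nPuncta),
        x_um = centersA[, 1] + centerUm[1], y_um = centersA[, 2] + centerUm[2],
        overlapped = NA
      ),
      if (params@nPuncta > 0) data.frame(
        channel = "markerB", index = seq_len(params@nPuncta),
        x_um = centersB[, 1] + centerUm[1], y_um = centersB[, 2] + centerUm[2],
        overlapped = overlapped
      )
    )
    rownames(truth) <- NULL
    list(image = img, truth = truth)
  })
}

# Uniform points in a disc of the given radius, centered on the origin.
.sampleInDisc <- function(n, radius) {
  if (n == 0 || radius <= 0) return(matrix(numeric(), 0, 2))
  r <- radius * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(a), r * sin(a))
}

# Uniform points in an annulus with rejection for a minimum mutual distance
# (also against `existing` centers).
.sampleInAnnulus <- function(n, rim, dMin, existing) {
  out <- matrix(NA_real_, n, 2)
  kept <- existing
  for (i in seq_len(n)) {
    for (iter in 1:2000) {
      r <- sqrt(stats::runif(1, rim[1]^2, rim[2]^2))
      a <- stats::runif(1, 0, 2 * pi)
      p <- c(r * cos(a), r * sin(a))
      if (nrow(kept) == 0 ||
          min((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) >= dMin^2) {
        out[i, ] <- p
        kept <- rbind(kept, p)
        break
      }
    }
    if (anyNA(out[i, ])) {
      stop("could not place puncta with the requested minimum separation; ",
           "reduce nPuncta or punctaSigma")
    }
  }
  out
}

# Add Gaussian spots (amplitude at center) onto an n x n grid, clipping each
# spot to a 4-sigma patch.
.paintPuncta <- function(n, s, centersUm, sigma, amp) {
  img <- matrix(0, n, n)
  h <- ceiling(4 * sigma / s)
  px <- .pixelCenters(n, 0, s)
  for (i in seq_len(nrow(centersUm))) {
    cxy <- centersUm[i, ]
    i0 <- max(1L, floor(cxy[1] / s - h)); i1 <- min(n, ceiling(cxy[1] / s + h))
    j0 <- max(1L, floor(cxy[2] / s - h)); j1 <- min(n, ceiling(cxy[2] / s + h))
    if (i0 > i1 || j0 > j1) next
    gx <- exp(-(px[i0:i1] - cxy[1])^2 / (2 * sigma^2))
    gy <- exp(-(px[j0:j1] - cxy[2])^2 / (2 * sigma^2))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amp * outer(gx, gy)
  }
  img
}
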