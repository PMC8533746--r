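# Centroid-distance classification of matrix molecules at the synapse.

#' Five-way cleft classification from centroid distances
#'
#' Classifies a matrix molecule (hyaluronan, HAS2, CD44, ...) relative to the
#' synaptic cleft from its centroid distances to the pre- and post-synaptic
#' marker centroids. The published distance rules are applied with their
#' printed strictness:
#'
#' \enumerate{
#'   \item not \code{present} (presence criterion failed): \code{ABSENT};
#'   \item \code{|dPre - dPost| > thetaDiff} (default 100 nm): preferential to
#'     the nearer compartment (\code{PRE_PREFERENTIAL} /
#'     \code{POST_PREFERENTIAL});
#'   \item both distances \code{< thetaIn} (default 50 nm): equidistantly in
#'     the cleft, \code{IN_CLEFT};
#'   \item otherwise: \code{NEAR_CLEFT}.
#' }
#'
#' The three published rules do not partition the distance plane (e.g. dPre =
#' 30, dPost = 80 satisfies none verbatim); the residual rule 4 assigns such
#' gap cases to \code{NEAR_CLEFT}, so that a synapse only counts as
#' preferential when the difference rule itself fires. The applied precedence
#' is recorded in the \code{ruleOrder} attribute of the result. See the
#' package vignette for the rationale.
#'
#' @param dPre,dPost numeric vectors, matrix-to-marker centroid distances in
#'   nm (>= 0). Recycled against each other.
#' @param present logical vector: outcome of the presence criterion.
#' @param params a [CleftClassParams-class].
#' @return character vector of classes with attribute \code{ruleOrder}.
#' @examples
#' classifyCleftLocalization(40, 45, TRUE)    # IN_CLEFT
#' classifyCleftLocalization(60, 95, TRUE)    # NEAR_CLEFT
#' classifyCleftLocalization(30, 160, TRUE)   # PRE_PREFERENTIAL
#' classifyCleftLocalization(0, 0, FALSE)     # ABSENT
#' @export
classifyCleftLocalization <- function(dPre, dPost, present = TRUE,
                                      params = CleftClassParams()) {
  stopifnot(is(params, "CleftClassParams"))
  n <- max(length(dPre), length(dPost), length(present))
  dPre <- rep_len(as.numeric(dPre), n)
  dPost <- rep_len(as.numeric(dPost), n)
  present <- rep_len(as.logical(present), n)
  bad <- present & (is.na(dPre) | is.na(dPost) | dPre < 0 | dPost < 0)
  if (any(bad)) stop("distances must be non-negative (and defined when present)")

  out <- rep("NEAR_CLEFT", n)
  pref <- present & abs(dPre - dPost) > params@thetaDiff
  out[pref & dPre < dPost] <- "PRE_PREFERENTIAL"
  out[pref & dPost <= dPre] <- "POST_PREFERENTIAL"
  inCleft <- present & !pref & dPre < params@thetaIn & dPost < params@thetaIn
  out[inCleft] <- "IN_CLEFT"
  out[!present] <- "ABSENT"
  attr(out, "ruleOrder") <- "absent > difference > in-cleft > near-cleft"
  out
}

#' Compartment assignment from centroid distances
#'
#' A matrix molecule counts as localized to a synaptic compartment when its
#' centroid lies within \code{thetaNear} (default 100 nm) of that
#' compartment's marker centroid; within 100 nm of both gives \code{BOTH},
#' within neither gives \code{NEITHER}.
#'
#' @param dPre,dPost numeric vectors, nm (>= 0); recycled.
#' @param thetaNear inclusion bound in nm.
#' @return character vector in \code{BOTH, PRE_ONLY, POST_ONLY, NEITHER}.
#' @examples
#' classifyCompartment(80, 90)    # BOTH
#' classifyCompartment(40, 250)   # PRE_ONLY
#' classifyCompartment(150, 150)  # NEITHER
#' @export
classifyCompartment <- function(dPre, dPost, thetaNear = 100) {
  n <- max(length(dPre), length(dPost))
  dPre <- rep_len(as.numeric(dPre), n)
  dPost <- rep_len(as.numeric(dPost), n)
  if (any(dPre < 0 | dPost < 0, na.rm = TRUE)) {
    stop("distances must be non-negative")
  }
  pre <- dPre <= thetaNear
  post <- dPost <= thetaNear
  out <- rep("NEITHER", n)
  out[pre & !post] <- "PRE_ONLY"
  out[!pre & post] <- "POST_ONLY"
  out[pre & post] <- "BOTH"
  out[is.na(pre) | is.na(post)] <- NA_character_
  out
}

#' Aggregate per-synapse classes into a distribution
#'
#' Counts and percentages per class over a batch of synapses — the
#' percent-stacked summary of where the matrix molecule sits across the
#' population. Percentages are computed as exact rational counts over n times
#' 100, so they sum to 100.
#'
#' @param x character vector of class labels, a list of
#'   [SynapseMeasurement-class] objects, or a data.frame with a
#'   \code{cleftClass} column.
#' @param levels class levels to tabulate; defaults to the five cleft classes
#'   when all labels are cleft classes, otherwise to the sorted unique labels.
#' @return data.frame with columns \code{class}, \code{count}, \code{percent}
#'   and attribute \code{n}.
#' @examples
#' aggregateDistribution(c("IN_CLEFT", "IN_CLEFT", "NEAR_CLEFT", "ABSENT"))
#' @export
aggregateDistribution <- function(x, levels = NULL) {
  if (is.list(x) && !is.data.frame(x) && length(x) &&
      is(x[[1]], "SynapseMeasurement")) {
    x <- vapply(x, cleftClass, character(1))
  } else if (is.data.frame(x)) {
    x <- x$cleftClass
  }
  x <- as.character(x)
  if (length(x) == 0) stop("no measurements to aggregate")
  if (anyNA(x)) stop("class labels contain NA")
  if (is.null(levels)) {
    levels <- if (all(x %in% .cleftClasses)) .cleftClasses else sort(unique(x))
  }
  if (!all(x %in% levels)) stop("labels outside 'levels'")
  counts <- as.integer(table(factor(x, levels = levels)))
  out <- data.frame(
    class = levels,
    count = counts,
    percent = 100 * counts / length(x),
    stringsAsFactors = FALSE
  )
  attr(out, "n") <- length(x)
  out
}
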