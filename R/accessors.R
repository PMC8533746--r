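# Accessors and show methods.

#' @describeIn LocalizationTable-class underlying data.frame
#' @param x,object a \code{LocalizationTable}
#' @export
setGeneric("locData", function(x) standardGeneric("locData"))

#' @rdname LocalizationTable-class
#' @export
setMethod("locData", "LocalizationTable", function(x) x@records)

#' @describeIn LocalizationTable-class number of localizations
#' @export
setGeneric("nLocalizations", function(x) standardGeneric("nLocalizations"))

#' @rdname LocalizationTable-class
#' @export
setMethod("nLocalizations", "LocalizationTable", function(x) nrow(x@records))

#' @describeIn LocalizationTable-class channel labels present in the table
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname LocalizationTable-class
#' @export
setMethod("channelNames", "LocalizationTable", function(x) {
  unique(x@records$channel)
})

#' @rdname LocalizationTable-class
#' @export
setMethod("show", "LocalizationTable", function(object) {
  df <- object@records
  cat(sprintf(
    "LocalizationTable: %d localizations, %d channel(s)\n",
    nrow(df), length(unique(df$channel))
  ))
  if (nrow(df)) {
    tab <- table(df$channel)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
})

#' @rdname SynapseMeasurement-class
#' @param object a \code{SynapseMeasurement}
#' @export
setMethod("show", "SynapseMeasurement", function(object) {
  cat("SynapseMeasurement\n")
  cat(sprintf(
    "  d_pre = %.1f nm, d_post = %.1f nm, separation = %.1f nm\n",
    object@dPre, object@dPost, object@separation
  ))
  cat(sprintf(
    "  cleft class: %s; compartment: %s (present: %s)\n",
    object@cleftClass, object@compartmentClass, object@present
  ))
})

#' @describeIn SynapseMeasurement-class cleft class label
#' @param x a \code{SynapseMeasurement}
#' @export
setGeneric("cleftClass", function(x) standardGeneric("cleftClass"))

#' @rdname SynapseMeasurement-class
#' @export
setMethod("cleftClass", "SynapseMeasurement", function(x) x@cleftClass)

#' @describeIn SynapseMeasurement-class compartment assignment
#' @export
setGeneric("compartmentClass", function(x) standardGeneric("compartmentClass"))

#' @rdname SynapseMeasurement-class
#' @export
setMethod("compartmentClass", "SynapseMeasurement", function(x) {
  x@compartmentClass
})

#' @describeIn SynapseMeasurement-class named distances (nm): dPre, dPost,
#'   separation
#' @export
setGeneric("cleftDistances", function(x) standardGeneric("cleftDistances"))

#' @rdname SynapseMeasurement-class
#' @export
setMethod("cleftDistances", "SynapseMeasurement", function(x) {
  c(dPre = x@dPre, dPost = x@dPost, separation = x@separation)
})

#' @describeIn SynapseMeasurement-class per-channel centroids (nm)
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname SynapseMeasurement-class
#' @export
setMethod("centroids", "SynapseMeasurement", function(x) x@centroids)

#' @describeIn SynapseMeasurement-class intensity profiles along the cleft
#'   axis
#' @export
setGeneric("cleftProfiles", function(x) standardGeneric("cleftProfiles"))

#' @rdname SynapseMeasurement-class
#' @export
setMethod("cleftProfiles", "SynapseMeasurement", function(x) x@profiles)

#' @describeIn GroundTruth-class intended class label
#' @param x,object a \code{GroundTruth}
#' @export
setGeneric("truthLabel", function(x) standardGeneric("truthLabel"))

#' @rdname GroundTruth-class
#' @export
setMethod("truthLabel", "GroundTruth", function(x) x@label)

#' @describeIn GroundTruth-class noiseless distances (nm)
#' @export
setMethod("cleftDistances", "GroundTruth", function(x) {
  c(dPre = x@dPre, dPost = x@dPost, separation = x@separation)
})

#' @rdname GroundTruth-class
#' @export
setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %s (d_pre = %.1f, d_post = %.1f, separation = %.1f nm)\n",
    object@label, object@dPre, object@dPost, object@separation
  ))
})

#' @rdname GroupComparison-class
#' @param object a \code{GroupComparison}
#' @export
setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison (n = %d vs %d)\n", object@nA, object@nB
  ))
  cat(sprintf(
    "  Shapiro-Wilk p: %.4g / %.4g (alpha = %g)\n",
    object@shapiroPA, object@shapiroPB, object@alpha
  ))
  cat(sprintf(
    "  %s: statistic = %.4g, two-sided p = %.4g\n",
    if (object@test == "t") "Student t-test" else "Mann-Whitney rank-sum",
    object@statistic, object@pValue
  ))
})

#' @describeIn GroupComparison-class chosen test ("t" or "mann-whitney")
#' @param x a \code{GroupComparison}
#' @export
setGeneric("chosenTest", function(x) standardGeneric("chosenTest"))

#' @rdname GroupComparison-class
#' @export
setMethod("chosenTest", "GroupComparison", function(x) x@test)

#' @describeIn GroupComparison-class two-sided p-value of the chosen test
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname GroupComparison-class
#' @export
setMethod("pValue", "GroupComparison", function(x) x@pValue)
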