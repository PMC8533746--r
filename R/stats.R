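# Normality-gated two-group comparison.

#' Compare two groups with a Shapiro-Wilk-gated test
#'
#' The two-group decision procedure used throughout the quantification: both
#' samples are screened with the Shapiro-Wilk normality test at \code{alpha};
#' when neither rejects, the groups are compared with a two-sided Student
#' t-test (equal variances by default), otherwise with a two-sided
#' Mann-Whitney rank-sum test. When only one group rejects normality the
#' rank-sum branch is taken (the conservative choice). A constant sample, for
#' which Shapiro-Wilk is undefined, is flagged and treated as non-normal.
#'
#' The Mann-Whitney branch uses the exact null distribution when both groups
#' have at most 20 observations and there are no ties, and the tie-corrected
#' normal approximation with continuity correction otherwise.
#'
#' @param a,b numeric samples, each with at least 3 observations.
#' @param alpha gate and test level (default 0.05).
#' @param welch use the Welch (unequal-variance) t-test on the parametric
#'   branch instead of the Student test.
#' @return a [GroupComparison-class].
#' @examples
#' compareGroups(c(5.1, 4.8, 5.4, 5.0, 5.2), c(6.0, 6.3, 5.9, 6.1, 6.2))
#' @export
compareGroups <- function(a, b, alpha = 0.05, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (anyNA(a) || anyNA(b)) stop("samples contain NA")
  if (length(a) < 3 || length(b) < 3) {
    stop("each sample needs at least 3 observations (Shapiro-Wilk is undefined below)")
  }
  swp <- function(x) {
    if (length(unique(x)) == 1L) {
      warning("constant sample: normality undefined, treated as non-normal")
      return(NA_real_)
    }
    stats::shapiro.test(x)$p.value
  }
  pA <- swp(a); pB <- swp(b)
  bothNormal <- !is.na(pA) && !is.na(pB) && pA > alpha && pB > alpha

  if (bothNormal) {
    tt <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
    res <- list(test = "t", statistic = unname(tt$statistic),
                pValue = tt$p.value)
  } else {
    nMax <- max(length(a), length(b))
    ties <- anyDuplicated(c(a, b)) > 0
    wt <- suppressWarnings(stats::wilcox.test(
      a, b, alternative = "two.sided",
      exact = nMax <= 20 && !ties, correct = TRUE
    ))
    res <- list(test = "mann-whitney", statistic = unname(wt$statistic),
                pValue = wt$p.value)
  }
  new("GroupComparison",
    nA = length(a), nB = length(b),
    shapiroPA = pA, shapiroPB = pB,
    test = res$test, statistic = res$statistic, pValue = res$pValue,
    alpha = alpha
  )
}
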