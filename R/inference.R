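#' Wald test for a (shrunken) log fold change
#'
#' The estimate divided by its standard error is compared to a standard
#' normal; two-sided p-values use the survival function for numerical
#' stability at large `|z|`.
#'
#' @param beta LFC estimate(s); any fixed log scale, as long as `se` matches.
#' @param se standard error(s), same scale as `beta`.
#' @return List with `z` and `p` (vectors).
#' @export
wald_test <- function(beta, se) {
  stopifnot(length(beta) == length(se))
  z <- beta / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  zero_se <- is.finite(beta) & !is.na(se) & se == 0
  if (any(zero_se & beta != 0)) {
    warning("zero standard error with non-zero estimate; p set to 0")
    z[zero_se & beta != 0] <- sign(beta[zero_se & beta != 0]) * Inf
    p[zero_se & beta != 0] <- 0
  }
  z[zero_se & beta == 0] <- 0
  p[zero_se & beta == 0] <- 1
  list(z = z, p = p)
}

#' Composite test: |LFC| greater than a threshold
#'
#' Tests the composite null `|beta| <= theta` by integrating a normal
#' centered at `theta` with scale `se` from `|beta|` outward, doubling,
#' and capping at 1. Reduces exactly to the Wald p-value at `theta = 0`.
#'
#' @inheritParams wald_test
#' @param theta non-negative threshold on the same log scale as `beta`.
#' @return Vector of p-values.
#' @export
composite_test_greater <- function(beta, se, theta) {
  stopifnot(theta >= 0, all(se > 0 | is.na(se)))
  pmin(1, 2 * stats::pnorm((abs(beta) - theta) / se, lower.tail = FALSE))
}

#' Composite test: |LFC| less than a threshold
#'
#' Tests the null `|beta| >= theta` as the maximum of two one-sided
#' normal tests centered at `+theta` and `-theta`. Must be applied to
#' unshrunken (maximum likelihood) estimates: a zero-centered prior pulls
#' estimates toward the alternative and would anti-conservatively favor
#' rejection.
#'
#' @inheritParams wald_test
#' @param theta positive threshold.
#' @param shrunken set TRUE by callers that applied an LFC prior; raises
#'   an error.
#' @return Vector of p-values.
#' @export
composite_test_less <- function(beta, se, theta, shrunken = FALSE) {
  stopifnot(theta > 0, all(se > 0 | is.na(se)))
  if (isTRUE(shrunken))
    stop("composite_test_less requires unshrunken LFC estimates ",
         "(disable the LFC prior)")
  pmax(stats::pnorm((beta - theta) / se),
       stats::pnorm((beta + theta) / se, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment over the non-missing p-values; missing entries
#' stay missing.
#'
#' @param pvalues vector of p-values in `[0, 1]`, possibly with `NA`s.
#' @return Vector of adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Automatic independent filtering
#'
#' Omits genes with low mean normalized count from multiple-testing
#' adjustment to increase power. Candidate thresholds are quantiles of
#' the filter statistic (`baseMean`); for each, BH adjustment is re-run on
#' the surviving genes and the threshold maximizing the number of
#' rejections at `target_fdr` is chosen (ties broken toward the smallest
#' threshold). Filtered genes receive a missing adjusted p-value. The
#' validity of filtering on mean count rests on its independence from the
#' null p-value (Basu's theorem for the NB family), which is a property of
#' the model, not something asserted at run time.
#'
#' @param base_mean per-gene mean of normalized counts.
#' @param pvalue per-gene p-values (`NA` for untested genes).
#' @param target_fdr adjusted-p cutoff whose rejection count is maximized.
#' @param quantiles candidate thresholds as quantiles of `base_mean`.
#' @return List with `padj`, `threshold` (value of `base_mean` cutoff),
#'   `quantile` (which quantile was chosen), `n_rejected` and the scanned
#'   `rejections` curve.
#' @export
independent_filter <- function(base_mean, pvalue, target_fdr = 0.1,
                               quantiles = seq(0, 0.95, by = 0.01)) {
  stopifnot(length(base_mean) == length(pvalue))
  testable <- !is.na(pvalue)
  if (!any(testable)) stop("no testable genes (all p-values missing)")
  cuts <- stats::quantile(base_mean[testable], quantiles, names = FALSE,
                          type = 7)
  rejections <- vapply(cuts, function(ct) {
    keep <- testable & base_mean >= ct
    if (!any(keep)) return(0L)
    sum(stats::p.adjust(pvalue[keep], method = "BH") < target_fdr)
  }, integer(1))
  best <- which.max(rejections)  # which.max returns the first (smallest) maximizer
  keep <- testable & base_mean >= cuts[best]
  padj <- rep(NA_real_, length(pvalue))
  padj[keep] <- stats::p.adjust(pvalue[keep], method = "BH")
  list(padj = padj, threshold = cuts[best], quantile = quantiles[best],
       n_rejected = rejections[best], rejections = rejections,
       candidates = cuts)
}
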