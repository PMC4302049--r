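#' Prior variance for the regularized logarithm
#'
#' A matrix of log2 ratios of each sample's normalized count (plus a
#' pseudocount of 1/2) to the gene's mean normalized count (plus 1/2) is
#' formed, and the prior variance is set by matching the 97.5% quantile of
#' a zero-centered normal to the 95% quantile of the absolute ratios.
#'
#' @param dataset a [count_dataset()] with normalization set.
#' @return Prior variance on the log2-squared scale (floored at 1e-6 for
#'   degenerate inputs).
#' @export
rlog_prior_width <- function(dataset) {
  nc <- normalized_counts(dataset)
  bar_mu <- rowMeans(nc)
  lfc <- log2((nc + 0.5) / (bar_mu + 0.5))
  q95 <- stats::quantile(abs(lfc), 0.95, names = FALSE, type = 7)
  max((q95 / stats::qnorm(0.975))^2, 1e-6)
}

#' Regularized logarithm transformation
#'
#' Transforms counts to an approximately homoskedastic log2 scale: each
#' gene is fit with an intercept plus one indicator per sample, a
#' zero-centered normal prior on the per-sample terms (width from
#' [rlog_prior_width()]), and dispersions fixed at the fitted trend
#' `alpha_tr(bar mu)`. The transformed values are the fitted
#' `log2 q = beta_0 + beta_j`: close to `log2(K/s)` for large counts,
#' shrunk together across samples for low counts. In blind mode (the
#' default) the experimental design is ignored and dispersions are
#' re-estimated treating all samples as replicates, which is what one
#' wants for unsupervised sample quality assessment.
#'
#' @param dataset a [count_dataset()]; size factors estimated if unset.
#' @param blind ignore the design when estimating the dispersion trend.
#' @param design formula used (only) for dispersion estimation when
#'   `blind = FALSE`.
#' @return Object of class `rlog_output`: list with `transformed`
#'   (genes x samples, log2), `intercept` (log2), `sample_lfc` (log2
#'   shrunken per-sample fold changes), `prior_sigma2` (log2-squared) and
#'   `blind`. All-zero genes transform to a row of zeros.
#' @export
rlog_transform <- function(dataset, blind = TRUE, design = NULL) {
  stopifnot(inherits(dataset, "count_dataset"))
  if (ncol(dataset$counts) < 2) stop("rlog needs at least two samples")
  if (is.null(dataset$size_factors) && is.null(dataset$norm_factors))
    dataset <- estimate_size_factors(dataset)
  K <- dataset$counts
  sf <- normalization_matrix(dataset)
  n <- nrow(K); m <- ncol(K)
  X_disp <- if (blind || is.null(design)) {
    matrix(1, m, 1, dimnames = list(NULL, "(Intercept)"))
  } else standard_design(design, dataset$sample_info)

  bar_mu <- mean_normalized_counts(dataset)
  genewise <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (bar_mu[i] == 0) next
    genewise[i] <- genewise_dispersion_mle(K[i, ], X_disp, sf[i, ])$alpha
  }
  trend <- tryCatch(fit_dispersion_trend(genewise, bar_mu),
                    error = function(e) NULL)
  if (is.null(trend)) {
    warning("dispersion trend unavailable; using a flat median trend")
    a0 <- stats::median(genewise, na.rm = TRUE)
    if (!is.finite(a0) || a0 <= 0) a0 <- 0.1
    trend <- list(trend_values = rep(a0, n))
  }
  alphas <- pmax(trend$trend_values, DISP_LOWER)

  sigma2_log2 <- rlog_prior_width(dataset)
  lambda_sample <- 1 / (sigma2_log2 * log(2)^2)  # penalty on the natural scale
  X <- cbind(1, diag(m))
  colnames(X) <- c("(Intercept)", colnames(K) %||% paste0("sample", seq_len(m)))
  lambda <- c(0, rep(lambda_sample, m))

  transformed <- matrix(0, n, m, dimnames = dimnames(K))
  intercept <- rep(NA_real_, n)
  sample_lfc <- matrix(NA_real_, n, m, dimnames = dimnames(K))
  for (i in seq_len(n)) {
    if (all(K[i, ] == 0)) next
    fit <- fit_nb_glm(K[i, ], X, sf[i, ], alpha = alphas[i], lambda = lambda)
    if (!fit$converged) next
    intercept[i] <- fit$beta_log2[1]
    sample_lfc[i, ] <- fit$beta_log2[-1]
    transformed[i, ] <- fit$beta_log2[1] + fit$beta_log2[-1]
  }
  structure(list(transformed = transformed, intercept = intercept,
                 sample_lfc = sample_lfc, prior_sigma2 = sigma2_log2,
                 blind = blind),
            class = "rlog_output")
}

#' @export
print.rlog_output <- function(x, ...) {
  cat("rlog_output:", nrow(x$transformed), "genes x", ncol(x$transformed),
      "samples (log2 scale);",
      if (x$blind) "blind" else "design-aware", "dispersion trend\n")
  cat(sprintf("  prior variance (log2^2): %.4g\n", x$prior_sigma2))
  invisible(x)
}
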