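#' Run the full differential expression pipeline
#'
#' Orchestrates the default analysis: median-of-ratios size factors,
#' three-step empirical Bayes dispersion estimation, maximum-likelihood
#' fits, Cook's-distance outlier handling (gene removal or count
#' replacement with refitting), LFC shrinkage on the expanded design with
#' a data-driven zero-centered prior, Wald or composite-threshold tests,
#' automatic independent filtering and Benjamini-Hochberg adjustment.
#'
#' @param dataset a [count_dataset()]; size factors are estimated if
#'   unset.
#' @param design one-sided formula over `sample_info` columns.
#' @param contrast list with elements `factor`, `numerator`,
#'   `denominator`; default: last factor in the design, last level versus
#'   first level.
#' @param test "standard" Wald test, "greaterAbs" (null `|LFC| <= theta`)
#'   or "lessAbs" (null `|LFC| >= theta`; requires `shrink_lfc = FALSE`).
#' @param lfc_threshold threshold `theta` on the log2 scale for composite
#'   tests.
#' @param target_fdr adjusted-p threshold optimized by independent
#'   filtering (default 0.1).
#' @param shrink_lfc apply the zero-centered LFC prior (default TRUE).
#' @param outlier_handling flag and act on Cook's-distance outliers.
#' @param independent_filtering filter low-count genes before adjustment.
#' @param verbose log fitted hyperparameters via `message()`.
#' @return A data.frame (class `nb_result`) with one row per gene:
#'   `baseMean`, `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `padj`,
#'   `maxCooks`, `status`. Attributes: `dispersion_model`, `lfc_prior`,
#'   `filter_threshold`, `contrast`, `size_factors`, `outlier_actions`.
#' @export
run_pipeline <- function(dataset, design = ~ condition, contrast = NULL,
                         test = c("standard", "greaterAbs", "lessAbs"),
                         lfc_threshold = 0, target_fdr = 0.1,
                         shrink_lfc = TRUE, outlier_handling = TRUE,
                         independent_filtering = TRUE, verbose = FALSE) {
  stopifnot(inherits(dataset, "count_dataset"))
  test <- match.arg(test)
  if (test == "lessAbs" && shrink_lfc)
    stop("testing the null of large LFCs requires shrink_lfc = FALSE: ",
         "the zero-centered prior would favor the alternative")
  if (test != "standard" && lfc_threshold < 0)
    stop("lfc_threshold must be non-negative")
  if (test == "lessAbs" && lfc_threshold <= 0)
    stop("lessAbs requires a positive lfc_threshold")
  say <- function(...) if (verbose) message(sprintf(...))

  if (is.null(dataset$size_factors) && is.null(dataset$norm_factors))
    dataset <- estimate_size_factors(dataset)
  if (!is.null(dataset$size_factors))
    say("size factors: %s", paste(signif(dataset$size_factors, 4), collapse = " "))
  info <- dataset$sample_info
  X_std <- standard_design(design, info)
  n <- nrow(dataset$counts); m <- ncol(dataset$counts); p <- ncol(X_std)

  dm <- estimate_dispersions(dataset, X_std)
  say("dispersion trend: a1 = %.4g, alpha0 = %.4g; sigma_d^2 = %.4g (s_lr = %.4g)",
      dm$a1, dm$alpha0, dm$sigma_d2, dm$s_lr)
  mle <- fit_mle_lfc(dataset, X_std, dm$final)

  status <- rep("ok", n)
  status[rowSums(dataset$counts) == 0] <- "all_zero"
  status[status == "ok" & !mle$converged] <- "not_converged"

  max_cooks <- rep(NA_real_, n)
  if (outlier_handling && m - p >= 1) {
    nc <- normalized_counts(dataset)
    cooks <- matrix(NA_real_, n, m)
    for (i in which(mle$converged)) {
      a_rob <- robust_mom_dispersion(nc[i, ])
      if (is.na(a_rob)) next
      cooks[i, ] <- cooks_distances(dataset$counts[i, ], mle$fits[[i]],
                                    a_rob)$distances
    }
    policy <- apply_outlier_policy(dataset, cooks, X_std)
    max_cooks <- policy$max_cooks
    status[policy$action == "removed" & status == "ok"] <- "outlier_removed"
    replaced <- which(policy$action == "replaced" & status == "ok")
    if (length(replaced)) {
      say("replacing outlier counts in %d gene(s) and refitting",
          length(replaced))
      dataset$counts[replaced, ] <- policy$counts[replaced, ]
      sf_mat <- normalization_matrix(dataset)
      for (i in replaced) {
        gw <- genewise_dispersion_mle(dataset$counts[i, ], X_std, sf_mat[i, ])
        if (!is.finite(gw$alpha)) next
        bar_i <- mean(dataset$counts[i, ] / sf_mat[i, ])
        tr_i <- dm$trend_fun(bar_i)
        dm$genewise[i] <- gw$alpha
        dm$trend_values[i] <- tr_i
        dm$outlier[i] <- log(gw$alpha) > log(tr_i) + 2 * dm$s_lr
        dm$final[i] <- if (dm$outlier[i]) gw$alpha else
          map_dispersion(dataset$counts[i, ], gw$mu0, X_std, tr_i,
                         dm$sigma_d2)$alpha
        refit <- fit_nb_glm(dataset$counts[i, ], X_std, sf_mat[i, ],
                            alpha = dm$final[i])
        mle$fits[[i]] <- refit
        mle$converged[i] <- refit$converged
        if (refit$converged) {
          mle$beta[i, ] <- refit$beta
          mle$mu[i, ] <- refit$mu
          mle$covariances[[i]] <- coefficient_covariance(refit)
        }
      }
      status[replaced] <- "outlier_replaced"
    }
    n_removed <- sum(status == "outlier_removed")
    if (n_removed) say("removed %d gene(s) with count outliers", n_removed)
  }

  # contrast selection
  facs <- design_factors(design, info)
  if (is.null(contrast)) {
    if (length(facs)) {
      f <- facs[length(facs)]
      levs <- levels(factor(info[[f]]))
      contrast <- list(factor = f, numerator = levs[length(levs)],
                       denominator = levs[1])
    } else {
      contrast <- list(coefficient = ncol(X_std))
    }
  }

  if (shrink_lfc) {
    X_work <- expanded_design(design, info)
    prior <- estimate_lfc_prior_width(mle$beta, X_std, X_work, info, design)
    say("LFC prior SDs (log2): %s",
        paste(signif(prior$sigma_log2[is.finite(prior$sigma_log2)], 4),
              collapse = " "))
    fit <- fit_map_lfc(dataset, X_work, dm$final, prior)
  } else {
    X_work <- X_std
    prior <- NULL
    fit <- mle
  }
  cvec <- if (!is.null(contrast$factor)) {
    contrast_vector(X_work, contrast$factor, contrast$numerator,
                    contrast$denominator)
  } else {
    v <- numeric(ncol(X_work)); v[contrast$coefficient] <- 1; v
  }

  est <- se <- rep(NA_real_, n)
  usable <- fit$converged & status %in% c("ok", "outlier_replaced")
  for (i in which(usable)) {
    est[i] <- sum(cvec * fit$beta[i, ])
    se[i] <- sqrt(drop(t(cvec) %*% fit$covariances[[i]] %*% cvec))
  }
  est_log2 <- ln_to_log2(est)
  se_log2 <- ln_to_log2(se)

  theta_ln <- log2_to_ln(lfc_threshold)
  ok <- is.finite(est) & is.finite(se) & se > 0
  pvalue <- stat <- rep(NA_real_, n)
  stat[ok] <- est[ok] / se[ok]
  pvalue[ok] <- switch(test,
    standard = wald_test(est[ok], se[ok])$p,
    greaterAbs = composite_test_greater(est[ok], se[ok], theta_ln),
    lessAbs = composite_test_less(est[ok], se[ok], theta_ln))

  base_mean <- mean_normalized_counts(dataset)
  filter_threshold <- NA_real_
  if (independent_filtering && any(!is.na(pvalue))) {
    filt <- independent_filter(base_mean, pvalue, target_fdr)
    padj <- filt$padj
    filter_threshold <- filt$threshold
    say("independent filtering threshold: baseMean >= %.4g (quantile %.2f), %d rejections",
        filt$threshold, filt$quantile, filt$n_rejected)
  } else {
    padj <- bh_adjust(pvalue)
  }
  status[status == "ok" & !is.na(pvalue) & is.na(padj)] <- "filtered"

  res <- data.frame(baseMean = base_mean, log2FoldChange = est_log2,
                    lfcSE = se_log2, stat = stat, pvalue = pvalue,
                    padj = padj, maxCooks = max_cooks, status = status,
                    row.names = dataset$gene_ids,
                    stringsAsFactors = FALSE)
  attr(res, "dispersion_model") <- dm
  attr(res, "lfc_prior") <- prior
  attr(res, "filter_threshold") <- filter_threshold
  attr(res, "contrast") <- contrast
  attr(res, "size_factors") <- dataset$size_factors
  attr(res, "test") <- test
  class(res) <- c("nb_result", "data.frame")
  res
}
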