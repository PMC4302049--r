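WIDE_PRIOR_SIGMA2_LN <- log(2)^2 * 1000  # "wide" prior: 1000 on the log2^2 scale
SIGMA_FLOOR_LN <- 1e-3 * log(2)

# quantile-matching width for one vector of MLE coefficients (natural log).
# Returns NA when too few usable values survive the extreme-LFC exclusion.
quantile_match_width <- function(beta, matching_p = 0.05,
                                 exclusion = log(2) * 10, min_mles = 10) {
  b <- abs(beta[is.finite(beta)])
  b <- b[b <= exclusion]
  if (length(b) < min_mles) return(NA_real_)
  sigma <- stats::quantile(b, 1 - matching_p, names = FALSE, type = 7) /
    stats::qnorm(1 - matching_p / 2)
  max(sigma, SIGMA_FLOOR_LN)
}

#' Estimate the zero-centered LFC prior width by quantile matching
#'
#' For each non-intercept coefficient the prior scale `sigma_r` is chosen
#' so that the `1 - p` empirical quantile of the absolute MLE fold changes
#' matches the `1 - p/2` quantile of `N(0, sigma_r^2)` (`p = 0.05` by
#' default). Values beyond 10 on the log2 scale are excluded as outliers.
#' For factors with more than two levels the widths of all pairwise level
#' contrasts are averaged, making the result independent of the base
#' level. When the design contains interactions, main-effect widths are
#' not estimated but set to a wide constant (1000 on the log2-squared
#' scale) so that main-effect shrinkage cannot masquerade as interaction
#' signal.
#'
#' @param mle_betas genes x coefficients matrix of maximum-likelihood
#'   coefficients from the standard design, natural-log scale.
#' @param std_design the standard design matrix the MLEs came from.
#' @param exp_design the expanded design the prior will be applied to.
#' @param sample_info per-sample metadata.
#' @param formula the design formula.
#' @param matching_p tail probability for quantile matching.
#' @return Object of class `lfc_prior`: list with `sigma2` (per
#'   expanded-design column, natural-log scale; `Inf` means unpenalized
#'   intercept), `lambda` (= 1/sigma2, 0 for the intercept),
#'   `sigma_log2` (per-column prior SDs, log2 scale) and `wide_terms`.
#' @export
estimate_lfc_prior_width <- function(mle_betas, std_design, exp_design,
                                     sample_info, formula,
                                     matching_p = 0.05) {
  mle_betas <- as.matrix(mle_betas)
  std_cols <- colnames(std_design)
  stopifnot(ncol(mle_betas) == ncol(std_design))
  colnames(mle_betas) <- std_cols
  exp_cols <- colnames(exp_design)
  p_exp <- ncol(exp_design)
  facs <- design_factors(formula, sample_info)
  inter <- has_interactions(formula)

  sigma2 <- rep(WIDE_PRIOR_SIGMA2_LN, p_exp)
  names(sigma2) <- exp_cols
  wide_terms <- character(0)
  fallback <- character(0)

  assign_width <- function(width, cols) {
    if (is.na(width)) {
      fallback <<- c(fallback, exp_cols[cols])
      width <- sqrt(WIDE_PRIOR_SIGMA2_LN)
    }
    sigma2[cols] <<- width^2
  }

  factor_cols_exp <- attr(exp_design, "factor_columns")
  for (v in facs) {
    cols <- factor_cols_exp[[v]]
    if (is.null(cols) || !length(cols)) next
    if (inter) {
      wide_terms <- c(wide_terms, exp_cols[cols])
      next  # main effects keep the wide prior under interactions
    }
    levs <- levels(factor(sample_info[[v]]))
    # standard-design coefficients: base level has implicit coefficient 0
    level_beta <- matrix(0, nrow(mle_betas), length(levs),
                         dimnames = list(NULL, levs))
    for (l in levs) {
      nm <- paste0(v, l)
      if (nm %in% std_cols) level_beta[, l] <- mle_betas[, nm]
    }
    pairs <- utils::combn(levs, 2, simplify = FALSE)
    widths <- vapply(pairs, function(pr)
      quantile_match_width(level_beta[, pr[1]] - level_beta[, pr[2]],
                           matching_p), numeric(1))
    assign_width(if (all(is.na(widths))) NA_real_ else mean(widths, na.rm = TRUE),
                 cols)
  }
  # numeric covariates and (for standard-design exception) interaction columns:
  # match columns shared between the standard and working design
  shared <- setdiff(intersect(exp_cols, std_cols), "(Intercept)")
  shared <- setdiff(shared, unlist(lapply(facs, function(v)
    exp_cols[factor_cols_exp[[v]]])))
  for (nm in shared) {
    if (inter && !grepl(":", nm, fixed = TRUE) &&
        nm %in% unlist(lapply(facs, function(v) paste0(v, levels(factor(sample_info[[v]])))))) {
      wide_terms <- c(wide_terms, nm)
      next
    }
    assign_width(quantile_match_width(mle_betas[, nm], matching_p),
                 which(exp_cols == nm))
  }
  if (length(fallback))
    warning("too few usable MLE fold changes for ",
            paste(unique(fallback), collapse = ", "),
            "; using the wide prior")
  lambda <- 1 / sigma2
  intercept <- which(exp_cols == "(Intercept)")
  lambda[intercept] <- 0
  sigma2[intercept] <- Inf
  structure(list(sigma2 = sigma2, lambda = lambda,
                 sigma_log2 = sqrt(sigma2) / log(2),
                 wide_terms = unique(wide_terms),
                 matching_p = matching_p),
            class = "lfc_prior")
}

#' Build an LFC prior with fixed widths
#'
#' Convenience constructor for a prior with user-chosen (rather than
#' data-estimated) widths, e.g. for sensitivity analyses.
#'
#' @param design the design matrix the prior applies to.
#' @param sigma2_log2 prior variance(s) on the log2-squared scale for all
#'   non-intercept columns (recycled).
#' @return An `lfc_prior` object as from [estimate_lfc_prior_width()].
#' @export
manual_lfc_prior <- function(design, sigma2_log2) {
  cols <- colnames(design)
  p <- ncol(design)
  sigma2 <- rep(sigma2_log2 * log(2)^2, length.out = p)
  intercept <- which(cols == "(Intercept)")
  if (!length(intercept)) intercept <- 1L
  lambda <- 1 / sigma2
  lambda[intercept] <- 0
  sigma2[intercept] <- Inf
  names(sigma2) <- names(lambda) <- cols
  structure(list(sigma2 = sigma2, lambda = lambda,
                 sigma_log2 = sqrt(sigma2) / log(2),
                 wide_terms = character(0), matching_p = NA_real_),
            class = "lfc_prior")
}

# fit every gene with a fixed design, per-gene dispersion and shared ridge
# penalty; the workhorse behind both MLE and MAP passes of the pipeline.
fit_all_genes <- function(dataset, design, alphas,
                          lambda = rep(0, ncol(design))) {
  X <- as.matrix(design)
  K <- dataset$counts
  sf <- normalization_matrix(dataset)
  n <- nrow(K); p <- ncol(X)
  beta <- matrix(NA_real_, n, p, dimnames = list(dataset$gene_ids, colnames(X)))
  mu <- matrix(NA_real_, n, ncol(K))
  converged <- logical(n)
  covariances <- vector("list", n)
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.finite(alphas[i]) || all(K[i, ] == 0)) next
    fit <- fit_nb_glm(K[i, ], X, sf[i, ], alpha = alphas[i], lambda = lambda)
    fits[[i]] <- fit
    if (!fit$converged) next
    beta[i, ] <- fit$beta
    mu[i, ] <- fit$mu
    converged[i] <- TRUE
    covariances[[i]] <- coefficient_covariance(fit)
  }
  list(beta = beta, mu = mu, converged = converged,
       covariances = covariances, fits = fits, design = X, lambda = lambda)
}

#' Maximum a posteriori (shrunken) LFC fits
#'
#' Fits every gene's NB GLM on the expanded design with the ridge penalty
#' implied by the zero-centered LFC prior, at the final dispersion values
#' (the MAP dispersion, or the gene-wise estimate for dispersion
#' outliers). Coefficient covariances are the ridge sandwich matrices.
#'
#' @param dataset a [count_dataset()] with normalization set.
#' @param exp_design expanded design matrix.
#' @param dispersions per-gene final dispersion values.
#' @param prior an [estimate_lfc_prior_width()] object.
#' @return List (class `lfc_fit`) with `beta` (genes x coefficients,
#'   natural log), `mu`, `converged`, `covariances` (per-gene matrices),
#'   `design`, `lambda`.
#' @export
fit_map_lfc <- function(dataset, exp_design, dispersions, prior) {
  stopifnot(inherits(prior, "lfc_prior"))
  out <- fit_all_genes(dataset, exp_design, dispersions, prior$lambda)
  structure(out, class = "lfc_fit")
}

#' Maximum-likelihood LFC fits on the standard design
#'
#' Unpenalized per-gene fits used for prior-width estimation, for Cook's
#' distances, and as the comparison point for shrinkage.
#'
#' @inheritParams fit_map_lfc
#' @param std_design standard (full-rank) design matrix.
#' @return Same structure as [fit_map_lfc()].
#' @export
fit_mle_lfc <- function(dataset, std_design, dispersions) {
  structure(fit_all_genes(dataset, std_design, dispersions),
            class = "lfc_fit")
}
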