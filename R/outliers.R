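#' Robust method-of-moments dispersion
#'
#' Dispersion estimate used inside Cook's distances, made robust against
#' the very outliers being hunted: `max((s_rob^2 - mu) / mu^2, 0)` where
#' `s_rob^2` is a robust variance of the normalized counts (the squared
#' MAD, scaled for normal consistency).
#'
#' @param norm_counts normalized counts for one gene.
#' @return Non-negative scalar, or `NA` when the gene has mean zero.
#' @export
robust_mom_dispersion <- function(norm_counts) {
  bar_mu <- mean(norm_counts)
  if (bar_mu == 0) return(NA_real_)
  s2 <- stats::mad(norm_counts)^2
  max((s2 - bar_mu) / bar_mu^2, 0)
}

#' Cook's distances for one gene
#'
#' Influence of each sample on the MLE coefficient vector:
#' `D_j = R_j^2 / p * h_jj / (1 - h_jj)^2`, with Pearson residuals
#' `R_j = (K_j - mu_j) / sqrt(mu_j + alpha * mu_j^2)` and hat diagonal
#' `h_jj` of `H = W^{1/2} X (X'WX)^{-1} X' W^{1/2}`. The robust
#' method-of-moments dispersion is used in both the variance function and
#' the weights, and the overdispersion scale of the classical formula is
#' fixed at 1.
#'
#' @param counts integer counts for the gene.
#' @param mle_fit converged `nb_glm_fit` without LFC prior (fitted means
#'   are taken from it).
#' @param alpha_rob robust dispersion from [robust_mom_dispersion()].
#' @return List with `distances` (per sample; `NA` where `h_jj = 1`) and
#'   `hat_diag`.
#' @export
cooks_distances <- function(counts, mle_fit, alpha_rob) {
  stopifnot(inherits(mle_fit, "nb_glm_fit"))
  if (!mle_fit$converged) stop("Cook's distances require a converged MLE fit")
  X <- mle_fit$design
  p <- ncol(X)
  mu <- mle_fit$mu
  a <- max(alpha_rob, 0)
  V <- mu + a * mu^2
  R <- (counts - mu) / sqrt(V)
  w <- 1 / (1 / mu + a)
  XtWXinv <- solve(crossprod(X, w * X))
  h <- w * rowSums((X %*% XtWXinv) * X)
  h <- pmin(pmax(h, 0), 1)
  D <- R^2 / p * h / (1 - h)^2
  D[h >= 1 - 1e-12] <- NA_real_
  list(distances = D, hat_diag = h)
}

#' Apply the count-outlier policy
#'
#' Samples whose Cook's distance exceeds the 0.99 quantile of
#' `F(p, m - p)` are flagged, except samples belonging to a design cell
#' (condition) with two or fewer replicates, which never contribute to
#' outlier detection. For a gene with a flagged sample:
#' \itemize{
#'   \item if the flagged sample's condition has six or fewer replicates,
#'     the whole gene is removed from further analysis (missing p-values,
#'     excluded from adjustment);
#'   \item with seven or more replicates, the outlying count is replaced
#'     by the trimmed mean (20\% each tail) of the gene's normalized
#'     counts scaled by the sample's size factor (rounded to an integer
#'     count), and the caller refits the gene end to end.
#' }
#'
#' @param dataset a [count_dataset()] with normalization set.
#' @param cooks genes x samples matrix of Cook's distances (`NA` allowed).
#' @param design standard design matrix (defines conditions as its unique
#'   rows and `p` as its column count).
#' @param trim trimmed-mean fraction per tail for replacement.
#' @return List with `action` (per gene: "none", "removed" or
#'   "replaced"), `counts` (matrix with replacements applied), `flags`
#'   (logical matrix), `cutoff`, and `max_cooks` (per-gene maximum over
#'   eligible samples).
#' @export
apply_outlier_policy <- function(dataset, cooks, design, trim = 0.2) {
  stopifnot(inherits(dataset, "count_dataset"))
  X <- as.matrix(design)
  m <- nrow(X); p <- ncol(X)
  cells <- apply(X, 1, paste, collapse = "\r")
  reps <- as.vector(table(cells)[cells])
  eligible <- reps >= 3   # <=2 replicates: no basis for outlier calls
  cutoff <- stats::qf(0.99, p, m - p)
  flags <- !is.na(cooks) & cooks > cutoff
  flags[, !eligible] <- FALSE
  max_cooks <- apply(cooks[, eligible, drop = FALSE], 1, function(d)
    if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE))
  if (!any(eligible)) max_cooks <- rep(NA_real_, nrow(cooks))

  counts <- dataset$counts
  sf_mat <- normalization_matrix(dataset)
  action <- rep("none", nrow(counts))
  for (i in which(rowSums(flags) > 0)) {
    flagged <- which(flags[i, ])
    if (any(reps[flagged] <= 6)) {
      action[i] <- "removed"
    } else {
      action[i] <- "replaced"
      y <- counts[i, ] / sf_mat[i, ]
      imputed <- mean(y, trim = trim)
      counts[i, flagged] <- round(imputed * sf_mat[i, flagged])
    }
  }
  list(action = action, counts = counts, flags = flags, cutoff = cutoff,
       max_cooks = max_cooks)
}
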