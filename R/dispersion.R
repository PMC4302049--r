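#' @importFrom stats dnbinom optimize glm Gamma median mad coef qnorm quantile
NULL

DISP_LOWER <- 1e-8
DISP_UPPER <- 30
LOG_DISP_RANGE <- c(log(DISP_LOWER), log(DISP_UPPER))

#' Method-of-moments starting dispersion
#'
#' A rough within-group moments estimate used only to seed the initial GLM
#' fit from which gene-wise dispersions are profiled. Groups are the cells
#' of the design (unique design rows); for each group with at least two
#' samples the estimate is `(var - mean)/mean^2` on normalized counts, and
#' the largest group value is returned, floored at a small positive value.
#'
#' @param counts integer count vector for one gene.
#' @param design design matrix (rows define the grouping cells).
#' @param normalization per-sample normalization factors.
#' @param floor lower bound returned for under-dispersed data.
#' @return Positive scalar.
#' @export
initial_dispersion_mom <- function(counts, design, normalization,
                                   floor = 1e-8) {
  y <- counts / normalization
  cells <- apply(as.matrix(design), 1, paste, collapse = "\r")
  ests <- vapply(split(y, cells), function(g) {
    if (length(g) < 2) return(NA_real_)
    mn <- mean(g)
    if (mn == 0) return(NA_real_)
    (stats::var(g) - mn) / mn^2
  }, numeric(1))
  if (all(is.na(ests))) {  # no replicated cell: pool everything
    mn <- mean(y)
    ests <- if (mn > 0) (stats::var(y) - mn) / mn^2 else NA_real_
  }
  max(max(ests, na.rm = TRUE), floor, na.rm = TRUE)
}

#' Cox-Reid adjusted profile log-likelihood of the dispersion
#'
#' The NB log-likelihood at fixed fitted means `mu0`, minus half the log
#' determinant of `X'WX` with IRLS weights `w_jj = 1/(1/mu_j + alpha)`.
#' The adjustment removes the downward bias that comes from plugging
#' fitted means into the likelihood (the GLM analogue of Bessel's
#' correction).
#'
#' @param alpha positive dispersion at which to evaluate.
#' @param counts integer count vector.
#' @param mu0 fitted means from an initial GLM fit (held fixed).
#' @param design design matrix used for the adjustment term.
#' @return Scalar adjusted log-likelihood.
#' @export
cr_adjusted_loglik <- function(alpha, counts, mu0, design) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  X <- as.matrix(design)
  w <- 1 / (1 / mu0 + alpha)
  ll <- sum(stats::dnbinom(counts, mu = mu0, size = 1 / alpha, log = TRUE))
  XtWX <- crossprod(X, w * X)
  ld <- determinant(XtWX, logarithm = TRUE)$modulus
  ll - 0.5 * as.numeric(ld)
}

# 1-D maximization over log(alpha) within the package bounds. The adjusted
# likelihood can be multimodal (e.g. a shallow interior bump next to a
# global maximum at the lower bound for underdispersed genes), so a coarse
# grid locates the global basin before a golden-section polish.
maximize_log_alpha <- function(fn, n_grid = 60L) {
  f_log <- function(la) fn(exp(la))
  grid <- seq(LOG_DISP_RANGE[1], LOG_DISP_RANGE[2], length.out = n_grid)
  vals <- vapply(grid, f_log, numeric(1))
  vals[!is.finite(vals)] <- -Inf
  k <- which.max(vals)
  lo <- grid[max(k - 1L, 1L)]
  hi <- grid[min(k + 1L, n_grid)]
  opt <- stats::optimize(f_log, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  la <- opt$maximum
  obj <- opt$objective
  at_bound <- FALSE
  for (b in c(1, 2)) {  # snap when a bound beats the interior polish
    bnd <- LOG_DISP_RANGE[b]
    if (vals[if (b == 1) 1L else n_grid] >= obj ||
        (abs(la - bnd) < 1e-2 && f_log(bnd) >= obj - 1e-10)) {
      la <- bnd
      at_bound <- TRUE
    }
  }
  list(alpha = exp(la), at_bound = at_bound)
}

#' Gene-wise dispersion by Cox-Reid adjusted maximum likelihood
#'
#' Fits an initial NB GLM at a method-of-moments dispersion to obtain
#' fitted means `mu0`, then maximizes [cr_adjusted_loglik()] over
#' `log(alpha)` within fixed bounds.
#'
#' @inheritParams initial_dispersion_mom
#' @param mu0 optional precomputed fitted means; estimated if NULL.
#' @return List with `alpha` (the gene-wise estimate), `mu0`, `at_bound`.
#' @export
genewise_dispersion_mle <- function(counts, design, normalization, mu0 = NULL) {
  if (all(counts == 0))
    return(list(alpha = NA_real_, mu0 = NULL, at_bound = FALSE))
  if (is.null(mu0)) {
    a0 <- max(initial_dispersion_mom(counts, design, normalization), 0.01)
    fit0 <- fit_nb_glm(counts, design, normalization, alpha = a0)
    if (!fit0$converged)
      return(list(alpha = NA_real_, mu0 = NULL, at_bound = FALSE))
    mu0 <- fit0$mu
  }
  opt <- maximize_log_alpha(function(a) cr_adjusted_loglik(a, counts, mu0, design))
  list(alpha = opt$alpha, mu0 = mu0, at_bound = opt$at_bound)
}

#' Fit the parametric dispersion-mean trend
#'
#' Fits `alpha_tr(mu) = a1/mu + alpha0` by iterated gamma-family GLM
#' regression of gene-wise dispersion estimates on `1/mu`. At each
#' iteration genes whose ratio of estimate to fitted value falls outside
#' `[1e-4, 15]` are excluded, and iteration stops when the summed squared
#' log-ratio of new to old coefficients drops below `1e-6`. Falls back to
#' a flat trend at the median gene-wise dispersion (with a warning) if the
#' gamma GLM fails or returns non-positive coefficients.
#'
#' @param genewise gene-wise dispersion estimates.
#' @param bar_mu mean normalized counts per gene.
#' @return List with `a1`, `alpha0`, `trend_values` (at the input
#'   `bar_mu`), `flat` (logical fallback flag) and `trend_fun`.
#' @export
fit_dispersion_trend <- function(genewise, bar_mu) {
  use <- is.finite(genewise) & is.finite(bar_mu) & bar_mu > 0 &
    genewise > 10 * DISP_LOWER
  if (sum(use) < 2)
    stop("need at least two usable genes to fit a dispersion trend")
  d <- genewise[use]
  mu <- bar_mu[use]
  flat <- function(msg) {
    warning("dispersion trend fit failed (", msg,
            "); using a flat median trend")
    a0 <- stats::median(d)
    list(a1 = 0, alpha0 = a0, flat = TRUE,
         trend_fun = function(x) rep(a0, length(x)),
         trend_values = rep(a0, length(bar_mu)))
  }
  coefs <- c(alpha0 = 0.1, a1 = 1)
  keep <- rep(TRUE, length(d))
  ok <- FALSE
  for (it in 1:10) {
    fit <- tryCatch(
      suppressWarnings(stats::glm(d[keep] ~ I(1 / mu[keep]),
                                  family = stats::Gamma(link = "identity"),
                                  start = unname(coefs))),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(stats::coef(fit))))
      return(flat("gamma GLM error"))
    new_coefs <- c(alpha0 = unname(stats::coef(fit)[1]),
                   a1 = unname(stats::coef(fit)[2]))
    if (any(new_coefs <= 0)) return(flat("non-positive coefficients"))
    pred <- new_coefs["a1"] / mu + new_coefs["alpha0"]
    ratio <- d / pred
    keep <- ratio >= 1e-4 & ratio <= 15
    if (sum(keep) < 2) return(flat("all genes excluded"))
    delta <- sum(log(new_coefs / coefs)^2)
    coefs <- new_coefs
    if (delta < 1e-6) {
      ok <- TRUE
      break
    }
  }
  if (!ok)
    warning("dispersion trend iteration cap reached; using last fit")
  a1 <- unname(coefs["a1"]); alpha0 <- unname(coefs["alpha0"])
  trend_fun <- function(x) a1 / x + alpha0
  list(a1 = a1, alpha0 = alpha0, flat = FALSE, trend_fun = trend_fun,
       trend_values = trend_fun(bar_mu))
}

#' Width of the log-normal dispersion prior
#'
#' The observed spread of log residuals around the trend, `s_lr` (a MAD,
#' scaled for normal consistency), mixes the true biological scatter of
#' dispersions with the sampling noise of the estimator. The sampling
#' variance of a log dispersion estimate is approximately
#' `trigamma((m - p)/2)` (the variance of the log of a chi-square variable
#' with `m - p` degrees of freedom), so the prior variance is
#' `sigma_d^2 = max(s_lr^2 - trigamma((m - p)/2), 0.25)`.
#'
#' With three or fewer residual degrees of freedom this subtraction is
#' unreliable, and `sigma_d^2` is instead selected on a grid by matching
#' the simulated density of `log chisq_{m-p} - log(m-p) + N(0, sigma_d^2)`
#' to the observed log-residual density via Kullback-Leibler divergence.
#'
#' @param genewise gene-wise dispersion estimates (usable genes only get
#'   used; non-finite entries are ignored).
#' @param trend_values trend dispersions at each gene's mean count.
#' @param m number of samples.
#' @param p number of design coefficients.
#' @return List with `sigma_d2` and `s_lr`.
#' @export
estimate_prior_variance <- function(genewise, trend_values, m, p) {
  if (m - p < 1) stop("need at least one residual degree of freedom")
  use <- is.finite(genewise) & is.finite(trend_values) &
    genewise > 10 * DISP_LOWER
  logres <- log(genewise[use]) - log(trend_values[use])
  s_lr <- stats::mad(logres)     # scaled by 1/qnorm(3/4) as usual
  df <- m - p
  if (df <= 3) {
    sigma_d2 <- kl_match_prior_variance(logres, df)
  } else {
    sigma_d2 <- max(s_lr^2 - trigamma(df / 2), 0.25)
  }
  list(sigma_d2 = sigma_d2, s_lr = s_lr)
}

# grid search over sigma_d^2 minimizing KL(observed || simulated)
kl_match_prior_variance <- function(logres, df, grid = 0.25 * 1.25^(0:24),
                                    n_sim = 1e5, n_bins = 500) {
  with_local_seed(20140522, {
    base_draw <- log(stats::rchisq(n_sim, df = df)) - log(df)
    norm_draw <- stats::rnorm(n_sim)
    kl <- vapply(grid, function(sd2) {
      sim <- base_draw + sqrt(sd2) * norm_draw
      rng <- range(c(logres, sim))
      breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1)
      p_obs <- tabulate(findInterval(logres, breaks, all.inside = TRUE), n_bins)
      q_sim <- tabulate(findInterval(sim, breaks, all.inside = TRUE), n_bins)
      p_obs <- p_obs / sum(p_obs)
      q_sim <- (q_sim + 0.5) / sum(q_sim + 0.5)  # smoothed to avoid log(0)
      keep <- p_obs > 0
      sum(p_obs[keep] * log(p_obs[keep] / q_sim[keep]))
    }, numeric(1))
    grid[which.min(kl)]
  })
}

#' Maximum a posteriori dispersion
#'
#' Maximizes the Cox-Reid adjusted log-likelihood plus the log density of
#' the log-normal prior centered at the trend,
#' `-(log alpha - log alpha_tr)^2 / (2 sigma_d^2)`, over `log(alpha)`.
#'
#' @inheritParams cr_adjusted_loglik
#' @param trend_value prior mean dispersion for this gene.
#' @param sigma_d2 prior variance of log dispersion.
#' @return List with `alpha` and `at_bound`.
#' @export
map_dispersion <- function(counts, mu0, design, trend_value, sigma_d2) {
  stopifnot(sigma_d2 > 0, trend_value > 0)
  lt <- log(trend_value)
  post <- function(a)
    cr_adjusted_loglik(a, counts, mu0, design) -
      (log(a) - lt)^2 / (2 * sigma_d2)
  maximize_log_alpha(post)
}

#' Flag dispersion outliers
#'
#' A gene is an outlier when its gene-wise estimate lies more than
#' `2 * s_lr` above the trend on the log scale. The rule is one-sided:
#' genes far below the curve are still shrunk (upward). Outlier genes keep
#' their gene-wise estimate as the final dispersion.
#'
#' @param genewise gene-wise dispersion estimates.
#' @param trend_values trend values per gene.
#' @param s_lr robust SD of log residuals from [estimate_prior_variance()].
#' @return Logical vector.
#' @export
classify_dispersion_outliers <- function(genewise, trend_values, s_lr) {
  stopifnot(s_lr > 0)
  flags <- log(genewise) > log(trend_values) + 2 * s_lr
  flags[!is.finite(genewise) | !is.finite(trend_values)] <- FALSE
  flags
}

#' Three-step empirical Bayes dispersion estimation
#'
#' Runs the full dispersion workflow for a dataset: gene-wise Cox-Reid
#' adjusted MLEs conditioned on an initial fit, the parametric trend
#' `a1/mu + alpha0`, the log-normal prior width, MAP estimates, and the
#' outlier escape.
#'
#' @param dataset a [count_dataset()] with size factors set.
#' @param design design matrix (standard, full rank).
#' @return Object of class `dispersion_model`: list with per-gene vectors
#'   `genewise`, `trend_values`, `map`, `final`, `outlier`, the scalars
#'   `a1`, `alpha0`, `sigma_d2`, `s_lr`, dims `m`, `p`, the matrix `mu0`
#'   of initial fitted means, and `trend_fun`.
#' @export
estimate_dispersions <- function(dataset, design) {
  stopifnot(inherits(dataset, "count_dataset"))
  X <- as.matrix(design)
  sf <- normalization_matrix(dataset)
  K <- dataset$counts
  n <- nrow(K); m <- ncol(K); p <- ncol(X)
  if (m - p < 1)
    stop("no residual degrees of freedom: m = ", m, ", p = ", p)
  bar_mu <- mean_normalized_counts(dataset)
  genewise <- rep(NA_real_, n)
  mu0 <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    if (bar_mu[i] == 0) next
    gw <- genewise_dispersion_mle(K[i, ], X, sf[i, ])
    genewise[i] <- gw$alpha
    if (!is.null(gw$mu0)) mu0[i, ] <- gw$mu0
  }
  # genes with a single positive count carry no dispersion information
  n_pos <- rowSums(K > 0)
  usable <- is.finite(genewise) & bar_mu > 0 & n_pos > 1
  trend <- fit_dispersion_trend(ifelse(usable, genewise, NA_real_), bar_mu)
  prior <- estimate_prior_variance(ifelse(usable, genewise, NA_real_),
                                   trend$trend_values, m, p)
  outlier <- classify_dispersion_outliers(genewise, trend$trend_values,
                                          prior$s_lr)
  map <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.finite(genewise[i]) || outlier[i]) next
    map[i] <- map_dispersion(K[i, ], mu0[i, ], X, trend$trend_values[i],
                             prior$sigma_d2)$alpha
  }
  final <- ifelse(outlier, genewise, map)
  structure(
    list(genewise = genewise, trend_values = trend$trend_values,
         a1 = trend$a1, alpha0 = trend$alpha0, flat_trend = trend$flat,
         trend_fun = trend$trend_fun, sigma_d2 = prior$sigma_d2,
         s_lr = prior$s_lr, map = map, final = final, outlier = outlier,
         mu0 = mu0, m = m, p = p),
    class = "dispersion_model")
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat("dispersion_model over", length(x$final), "genes\n")
  cat(sprintf("  trend: alpha_tr(mu) = %.4g/mu + %.4g%s\n", x$a1, x$alpha0,
              if (x$flat_trend) "  [flat fallback]" else ""))
  cat(sprintf("  prior: sigma_d^2 = %.4g (s_lr = %.4g)\n", x$sigma_d2, x$s_lr))
  cat(sprintf("  dispersion outliers: %d\n", sum(x$outlier, na.rm = TRUE)))
  invisible(x)
}
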