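#' Negative binomial log probability mass
#'
#' Log pmf of the NB distribution in the mean/dispersion parameterization
#' used throughout the package: mean `mu`, dispersion `alpha`, variance
#' `mu + alpha * mu^2` (i.e. `size = 1/alpha`).
#'
#' @param k non-negative integer count (vectorized).
#' @param mu positive mean.
#' @param alpha positive dispersion.
#' @return Log probability mass.
#' @export
nb_log_pmf <- function(k, mu, alpha) {
  if (any(!is_wholenumber(k)) || any(k < 0))
    stop("k must be a non-negative integer")
  stopifnot(all(mu > 0), all(alpha > 0))
  stats::dnbinom(round(k), mu = mu, size = 1 / alpha, log = TRUE)
}

MU_FLOOR <- 1e-10

# penalized NB log-likelihood: sum log f_NB + sum(-lambda * beta^2 / 2)
nb_penalized_loglik <- function(counts, mu, alpha, beta, lambda) {
  sum(stats::dnbinom(counts, mu = pmax(mu, MU_FLOOR), size = 1 / alpha, log = TRUE)) -
    sum(lambda * beta^2) / 2
}

#' Fit a negative binomial GLM by iteratively reweighted (ridge) regression
#'
#' Fits log-link NB regression for one gene's counts at fixed dispersion
#' `alpha`, optionally with a ridge penalty `lambda_r = 1/sigma_r^2` per
#' coefficient (zero = unpenalized, e.g. the intercept). The update is
#' `beta <- (X'WX + diag(lambda))^{-1} X'W z` with weights
#' `w_jj = 1/(1/mu_j + alpha)` and working response
#' `z_j = log(mu_j/s_j) + (K_j - mu_j)/mu_j`, guarded by step halving so the
#' penalized log-likelihood never decreases across accepted iterations.
#'
#' @param counts non-negative integer vector of length m.
#' @param design m x p design matrix.
#' @param normalization per-sample size factors `s_j` (length m) or the
#'   gene's row of an `s_ij` matrix.
#' @param alpha positive dispersion used in the fit.
#' @param lambda ridge penalties per coefficient (length p), natural-log
#'   scale; default all zero (maximum likelihood).
#' @param beta_init optional starting coefficients; default ridge least
#'   squares of `log(K/s + 0.5)` on the design.
#' @param tol relative penalized-deviance convergence tolerance.
#' @param max_iter iteration cap.
#' @return Object of class `nb_glm_fit`: list with `beta` (natural-log
#'   scale), `beta_log2`, `mu`, `weights`, `loglik` (penalized), `iter`,
#'   `converged`, plus the inputs needed downstream (`design`, `lambda`,
#'   `alpha`, `normalization`).
#' @export
fit_nb_glm <- function(counts, design, normalization, alpha,
                       lambda = rep(0, ncol(design)),
                       beta_init = NULL, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(design)
  m <- length(counts)
  p <- ncol(X)
  stopifnot(nrow(X) == m, length(normalization) == m, alpha > 0,
            length(lambda) == p, all(lambda >= 0))
  s <- normalization
  fail <- function() {
    structure(list(beta = rep(NA_real_, p), beta_log2 = rep(NA_real_, p),
                   mu = rep(NA_real_, m), weights = rep(NA_real_, m),
                   loglik = NA_real_, iter = 0L, converged = FALSE,
                   design = X, lambda = lambda, alpha = alpha,
                   normalization = s),
              class = "nb_glm_fit")
  }
  if (all(counts == 0)) return(fail())

  if (is.null(beta_init)) {
    y0 <- log(counts / s + 0.5)
    XtX <- crossprod(X) + diag(lambda + 1e-8, p)
    beta <- drop(solve(XtX, crossprod(X, y0)))
  } else beta <- beta_init

  mu <- pmax(s * exp(drop(X %*% beta)), MU_FLOOR)
  obj <- nb_penalized_loglik(counts, mu, alpha, beta, lambda)
  if (!is.finite(obj)) return(fail())
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    w <- 1 / (1 / mu + alpha)
    z <- log(mu / s) + (counts - mu) / mu
    XtWX <- crossprod(X, w * X)
    rhs <- crossprod(X, w * z)
    beta_new <- tryCatch(drop(solve(XtWX + diag(lambda, p), rhs)),
                         error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) break
    # step halving: accept the first step that does not decrease the objective
    step <- beta_new - beta
    accepted <- FALSE
    frac <- 1
    for (h in 1:20) {
      cand <- beta + frac * step
      mu_c <- pmax(s * exp(drop(X %*% cand)), MU_FLOOR)
      obj_c <- nb_penalized_loglik(counts, mu_c, alpha, cand, lambda)
      if (is.finite(obj_c) && obj_c >= obj - 1e-12) {
        accepted <- TRUE
        break
      }
      frac <- frac / 2
    }
    if (!accepted) break
    rel_change <- abs(obj_c - obj) / (abs(obj) + 0.1)
    beta <- cand
    mu <- mu_c
    obj <- obj_c
    if (rel_change < tol) {
      converged <- TRUE
      break
    }
  }
  w <- 1 / (1 / mu + alpha)
  structure(list(beta = beta, beta_log2 = ln_to_log2(beta), mu = mu,
                 weights = w, loglik = obj, iter = iter,
                 converged = converged, design = X, lambda = lambda,
                 alpha = alpha, normalization = s),
            class = "nb_glm_fit")
}

#' Coefficient covariance of a (ridge-penalized) NB GLM fit
#'
#' Sandwich covariance
#' \eqn{\Sigma = (X'WX + \lambda I)^{-1} (X'WX) (X'WX + \lambda I)^{-1}},
#' which reduces to the usual \eqn{(X'WX)^{-1}} when all penalties are zero.
#' Returned on the natural-log scale; divide standard errors by `log(2)`
#' for the log2 scale (see [contrast_estimate()]).
#'
#' @param fit an `nb_glm_fit`.
#' @return Symmetric p x p matrix of class `coefficient_covariance`.
#' @export
coefficient_covariance <- function(fit) {
  stopifnot(inherits(fit, "nb_glm_fit"))
  if (!fit$converged) stop("cannot compute covariance of a non-converged fit")
  X <- fit$design
  XtWX <- crossprod(X, fit$weights * X)
  p <- ncol(X)
  ridge <- XtWX + diag(fit$lambda, p)
  inv <- tryCatch(solve(ridge), error = function(e)
    stop("X'WX + lambda*I is singular (rank-deficient design with an ",
         "unpenalized coefficient)"))
  if (all(fit$lambda == 0)) {
    # guard against solve() succeeding numerically on a truly singular matrix
    if (rcond(XtWX) < 1e-12)
      stop("X'WX is rank deficient and no ridge penalty is present")
  }
  sigma <- inv %*% XtWX %*% inv
  sigma <- (sigma + t(sigma)) / 2
  structure(sigma, class = c("coefficient_covariance", "matrix"))
}

#' Contrast estimate and standard error
#'
#' Computes \eqn{\beta^c = c'\beta} and \eqn{SE(\beta^c) = \sqrt{c'\Sigma c}}
#' for a numeric contrast, reporting on the log2 scale.
#'
#' @param fit an `nb_glm_fit`.
#' @param covariance matrix from [coefficient_covariance()]; computed if NULL.
#' @param contrast numeric vector of length p.
#' @return List with `estimate` and `se` (both log2 scale) and
#'   `estimate_ln`, `se_ln` (natural-log scale).
#' @export
contrast_estimate <- function(fit, contrast, covariance = NULL) {
  stopifnot(inherits(fit, "nb_glm_fit"))
  if (length(contrast) != length(fit$beta))
    stop("contrast length ", length(contrast), " != number of coefficients ",
         length(fit$beta))
  if (is.null(covariance)) covariance <- coefficient_covariance(fit)
  est <- sum(contrast * fit$beta)
  se <- sqrt(drop(t(contrast) %*% covariance %*% contrast))
  list(estimate = ln_to_log2(est), se = ln_to_log2(se),
       estimate_ln = est, se_ln = se)
}
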