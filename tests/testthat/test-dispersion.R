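test_that("method-of-moments starting dispersion follows the group formula", {
  X <- cbind(1, rep(c(0, 1), each = 3))
  # constant groups: under-dispersed, floored
  expect_equal(initial_dispersion_mom(rep(10, 6), X, rep(1, 6)), 1e-8)
  # hand case in one group: counts (0, 10, 20), mean 10, var 100 -> 0.9
  k <- c(0, 10, 20, 10, 10, 10)
  expect_equal(initial_dispersion_mom(k, X, rep(1, 6)), (100 - 10) / 100)
})

test_that("Cox-Reid adjustment assembles correctly and is monotone in alpha", {
  # single sample, intercept design: adjustment = -0.5 * log(w11)
  k <- 7; mu0 <- 5; a <- 0.3
  X1 <- matrix(1, 1, 1)
  expect_equal(cr_adjusted_loglik(a, k, mu0, X1),
               dnbinom(k, mu = mu0, size = 1 / a, log = TRUE) -
                 0.5 * log(1 / (1 / mu0 + a)),
               tolerance = 1e-12)
  # adjustment term (-0.5 log det X'WX) increases as alpha grows (w shrinks)
  adj <- function(a) -0.5 * log(det(crossprod(X1, (1 / (1 / mu0 + a)) * X1)))
  alphas <- c(0.01, 0.1, 1, 5)
  expect_true(all(diff(vapply(alphas, adj, numeric(1))) > 0))
  expect_error(cr_adjusted_loglik(-1, k, mu0, X1), "positive")
})

test_that("adjusted and unadjusted dispersion MLEs agree for large samples", {
  withr::with_seed(91, {
    m <- 200
    k <- rnbinom(m, mu = 100, size = 1 / 0.2)
    X <- matrix(1, m, 1)
    gw <- genewise_dispersion_mle(k, X, rep(1, m))
    un <- optimize(function(la) nb_loglik_alpha(exp(la), k, gw$mu0),
                   c(log(1e-8), log(30)), maximum = TRUE, tol = 1e-8)
    expect_equal(gw$alpha, exp(un$maximum), tolerance = 0.05)
  })
})

test_that("gene-wise MLE matches a dense grid search over log alpha", {
  cd <- make_two_group_dataset(n = 8, m = 6, seed = 17, alpha = 0.3)
  X <- standard_design(~ condition, cd$sample_info)
  grid <- seq(-18, 6, by = 1e-3)
  for (i in seq_len(8)) {
    k <- cd$counts[i, ]
    gw <- genewise_dispersion_mle(k, X, rep(1, 6))
    f <- function(la) cr_adjusted_loglik(exp(la), k, gw$mu0, X)
    vals <- vapply(grid, f, numeric(1))
    best <- grid[which.max(vals)]
    # same basin: objective at our maximizer is >= grid optimum
    expect_gte(f(log(gw$alpha)), max(vals) - 1e-6)
    if (abs(best) < 17)  # interior solution: location agrees too
      expect_equal(log(gw$alpha), best, tolerance = 5e-3)
  }
})

test_that("gene-wise MLE recovers a known dispersion in Monte Carlo", {
  withr::with_seed(55, {
    m <- 50
    X <- matrix(1, m, 1)
    ests <- replicate(400, {
      k <- rnbinom(m, mu = 100, size = 1 / 0.2)
      genewise_dispersion_mle(k, X, rep(1, m))$alpha
    })
    expect_equal(median(ests), 0.2, tolerance = 0.1)
  })
  # Poisson data: estimate at or near the lower bound
  withr::with_seed(56, {
    k <- rpois(20, 50)
    gw <- genewise_dispersion_mle(k, matrix(1, 20, 1), rep(1, 20))
    expect_lt(gw$alpha, 1e-3)
  })
})

test_that("dispersion trend recovers noiseless and flat generating curves", {
  bar_mu <- exp(seq(log(1), log(5000), length.out = 300))
  gw <- 3 / bar_mu + 0.05
  tr <- fit_dispersion_trend(gw, bar_mu)
  expect_equal(tr$a1, 3, tolerance = 0.01)
  expect_equal(tr$alpha0, 0.05, tolerance = 0.01)

  tr_flat <- suppressWarnings(
    fit_dispersion_trend(withr::with_seed(3, 0.1 * exp(rnorm(300, 0, 1e-6))),
                         bar_mu))
  expect_lt(tr_flat$a1, 0.01)
  expect_equal(tr_flat$alpha0, 0.1, tolerance = 0.01)
})

test_that("the ratio rule shields the trend from a planted dispersion outlier", {
  withr::with_seed(77, {
    bar_mu <- exp(runif(200, 0, 8))
    gw <- (3 / bar_mu + 0.05) * exp(rnorm(200, 0, 0.2))
    base <- fit_dispersion_trend(gw, bar_mu)
    gw_out <- gw
    gw_out[17] <- 1000 * (3 / bar_mu[17] + 0.05)
    pl <- fit_dispersion_trend(gw_out, bar_mu)
    expect_lt(abs(pl$a1 - base$a1) / base$a1, 0.01)
    expect_lt(abs(pl$alpha0 - base$alpha0) / base$alpha0, 0.01)
  })
})

test_that("prior variance subtracts the trigamma sampling variance", {
  # craft residuals with mad^2 exactly 2.0 around a flat trend
  res0 <- qnorm(seq(0.01, 0.99, length.out = 99))
  res <- res0 * sqrt(2) / mad(res0)
  gw <- 0.1 * exp(res)
  pv <- estimate_prior_variance(gw, rep(0.1, 99), m = 12, p = 2)
  expect_equal(pv$s_lr^2, 2, tolerance = 1e-10)
  # 2.0 - psi1(5); psi1(5) = pi^2/6 - 1 - 1/4 - 1/9 - 1/16
  expect_equal(pv$sigma_d2, 2 - 0.221323, tolerance = 1e-4)

  # below the sampling noise: floored at 0.25
  res_small <- res0 * sqrt(0.3) / mad(res0)
  pv2 <- estimate_prior_variance(0.1 * exp(res_small), rep(0.1, 99),
                                 m = 6, p = 2)
  expect_identical(pv2$sigma_d2, 0.25)
})

test_that("log chi-square variance equals the trigamma function (Monte Carlo)", {
  withr::with_seed(101, {
    for (f in c(4, 10, 40)) {
      x <- log(rchisq(20000, df = f))
      v <- var(x)
      se <- sd((x - mean(x))^2) / sqrt(20000)
      expect_lt(abs(v - trigamma(f / 2)), 3 * se + 1e-3)
    }
  })
})

test_that("few residual degrees of freedom trigger density matching", {
  withr::with_seed(140, {
    df <- 2
    true_sd2 <- 1.0
    res <- log(rchisq(3000, df)) - log(df) + rnorm(3000, 0, sqrt(true_sd2))
    gw <- 0.1 * exp(res)
    pv <- estimate_prior_variance(gw, rep(0.1, 3000), m = 3, p = 1)
    expect_gte(pv$sigma_d2, 0.5)
    expect_lte(pv$sigma_d2, 2.0)
  })
})

test_that("MAP dispersion interpolates between the trend and the gene-wise MLE", {
  cd <- make_two_group_dataset(n = 30, m = 6, seed = 18, alpha = 0.4)
  X <- standard_design(~ condition, cd$sample_info)
  for (i in 1:10) {
    k <- cd$counts[i, ]
    if (all(k == 0)) next
    gw <- genewise_dispersion_mle(k, X, rep(1, 6))
    trend <- 0.1
    # flat prior limit
    m_flat <- map_dispersion(k, gw$mu0, X, trend, sigma_d2 = 1e8)
    expect_equal(log(m_flat$alpha), log(gw$alpha), tolerance = 1e-2)
    # point prior limit
    m_point <- map_dispersion(k, gw$mu0, X, trend, sigma_d2 = 1e-8)
    expect_equal(log(m_point$alpha), log(trend), tolerance = 1e-2)
    # intermediate prior lands between (unimodal case, checked loosely)
    m_mid <- map_dispersion(k, gw$mu0, X, trend, sigma_d2 = 0.5)
    lo <- min(log(gw$alpha), log(trend)) - 1e-6
    hi <- max(log(gw$alpha), log(trend)) + 1e-6
    expect_gte(log(m_mid$alpha), lo)
    expect_lte(log(m_mid$alpha), hi)
  }
})

test_that("dispersion outlier rule is one-sided at 2 s_lr", {
  trend <- rep(0.1, 3)
  s_lr <- 0.5
  gw <- 0.1 * exp(c(2.1, 1.9, -5) * s_lr)
  flags <- classify_dispersion_outliers(gw, trend, s_lr)
  expect_identical(flags, c(TRUE, FALSE, FALSE))
})

test_that("full dispersion model shrinks less with more samples and beats the MLE", {
  fit_rmse <- function(m, seed) {
    sim <- simulate_dataset(n_genes = 250, m = m, de_fraction = 0, seed = seed)
    ds <- estimate_size_factors(sim$dataset)
    X <- standard_design(~ condition, ds$sample_info)
    dm <- estimate_dispersions(ds, X)
    ok <- is.finite(dm$map) & is.finite(dm$genewise)
    list(shrink = mean(abs(log(dm$map[ok]) - log(dm$genewise[ok]))),
         rmse_map = sqrt(mean((log(dm$final[ok]) -
                                 log(sim$true_dispersion[ok]))^2)),
         rmse_gw = sqrt(mean((log(dm$genewise[ok]) -
                                log(sim$true_dispersion[ok]))^2)),
         dm = dm)
  }
  r6 <- fit_rmse(6, 301)
  r20 <- fit_rmse(20, 302)
  # shrinkage weakens as information grows
  expect_lt(r20$shrink, r6$shrink)
  # moderated estimates beat gene-wise MLEs in log-space RMSE at m=6
  expect_lt(r6$rmse_map, r6$rmse_gw)
  # outlier genes keep their gene-wise value bit for bit
  dm <- r6$dm
  if (any(dm$outlier, na.rm = TRUE))
    expect_identical(unname(dm$final[which(dm$outlier)]),
                     unname(dm$genewise[which(dm$outlier)]))
})
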