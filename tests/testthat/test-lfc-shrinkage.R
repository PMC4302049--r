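test_that("expanded designs carry one indicator per level plus an intercept", {
  info <- data.frame(condition = factor(c("A", "A", "B", "B")))
  X <- expanded_design(~ condition, info)
  expect_equal(dim(X), c(4, 3))
  expect_equal(qr(X)$rank, 2)
  expect_equal(colnames(X), c("(Intercept)", "conditionA", "conditionB"))
  expect_equal(rowSums(X[, 2:3]), rep(1, 4), ignore_attr = TRUE)

  info3 <- data.frame(g = factor(c("a", "b", "c", "a")))
  X3 <- expanded_design(~ g, info3)
  expect_equal(ncol(X3), 4)
  # relabeling which level comes first only permutes columns
  info3b <- data.frame(g = factor(c("a", "b", "c", "a"),
                                  levels = c("c", "b", "a")))
  X3b <- expanded_design(~ g, info3b)
  expect_equal(X3[, sort(colnames(X3))], X3b[, sort(colnames(X3b))],
               ignore_attr = TRUE)
})

test_that("interactions between two-level factors use a standard design", {
  info <- data.frame(f = factor(rep(c("a", "b"), each = 4)),
                     g = factor(rep(c("x", "y"), 4)))
  X <- expanded_design(~ f + g + f:g, info)
  expect_false(attr(X, "expanded"))
  expect_equal(ncol(X), 4)
  expect_equal(qr(X)$rank, 4)
  # a three-level factor keeps the expanded construction
  info2 <- data.frame(f = factor(rep(c("a", "b", "c"), each = 4)),
                      g = factor(rep(c("x", "y"), 6)))
  X2 <- expanded_design(~ f + g + f:g, info2)
  expect_true(attr(X2, "expanded"))
})

test_that("factor levels with no samples are rejected", {
  info <- data.frame(condition = factor(c("A", "A", "B", "B"),
                                        levels = c("A", "B", "C")))
  expect_error(standard_design(~ condition, info), "zero samples")
})

test_that("quantile matching recovers the prior width", {
  info <- two_group_info(4)
  Xs <- standard_design(~ condition, info)
  Xe <- expanded_design(~ condition, info)
  # crafted MLEs whose 95% |quantile| is exactly 2 * qnorm(0.975)
  b0 <- qnorm(seq(0.005, 0.995, length.out = 2001))
  b <- b0 * 3.919928 / quantile(abs(b0), 0.95, type = 7)
  mle <- cbind(0, b)
  prior <- estimate_lfc_prior_width(mle, Xs, Xe, info, ~ condition)
  expect_equal(unname(prior$sigma2["conditionB"]), 4, tolerance = 1e-6)
  expect_equal(unname(prior$sigma2["conditionA"]), 4, tolerance = 1e-6)
  expect_identical(unname(prior$lambda["(Intercept)"]), 0)

  # Monte Carlo: normal MLEs recover sigma within 2%
  withr::with_seed(61, {
    mle_mc <- cbind(0, rnorm(1e5, 0, 2))
    pr_mc <- estimate_lfc_prior_width(mle_mc, Xs, Xe, info, ~ condition)
    expect_equal(unname(sqrt(pr_mc$sigma2["conditionB"])), 2,
                 tolerance = 0.02)
  })

  # all MLEs beyond the exclusion bound: wide-prior fallback with warning
  mle_ext <- cbind(0, rep(log(2) * 12, 50))
  expect_warning(
    pr_ext <- estimate_lfc_prior_width(mle_ext, Xs, Xe, info, ~ condition),
    "wide prior")
  expect_equal(unname(pr_ext$sigma2["conditionB"]), log(2)^2 * 1000)
})

test_that("interaction designs force wide main-effect priors", {
  info <- data.frame(f = factor(rep(c("a", "b"), each = 4)),
                     g = factor(rep(c("x", "y"), 4)))
  Xs <- standard_design(~ f + g + f:g, info)
  Xe <- expanded_design(~ f + g + f:g, info)
  mle <- withr::with_seed(5, matrix(rnorm(200 * 4, 0, 0.5), 200, 4))
  prior <- estimate_lfc_prior_width(mle, Xs, Xe, info, ~ f + g + f:g)
  expect_equal(unname(prior$sigma2["fb"]), log(2)^2 * 1000)
  expect_equal(unname(prior$sigma2["gy"]), log(2)^2 * 1000)
  # the interaction column is estimated from the data, not set wide
  expect_lt(prior$sigma2["fb:gy"], 10)
})

test_that("the prior pulls low-information genes harder", {
  # identical counts, dispersion 0.01 vs 1.0: high-dispersion gene shrinks more
  k <- c(100, 110, 90, 200, 220, 180)
  info <- two_group_info(6)
  Xe <- expanded_design(~ condition, info)
  cd <- count_dataset(rbind(k, k), info)
  cd$size_factors <- rep(1, 6)
  prior <- manual_lfc_prior(Xe, sigma2_log2 = 0.5)
  fit <- fit_map_lfc(cd, Xe, dispersions = c(0.01, 1.0), prior)
  cvec <- contrast_vector(Xe, "condition", "B", "A")
  lfc1 <- sum(cvec * fit$beta[1, ])
  lfc2 <- sum(cvec * fit$beta[2, ])
  expect_lt(abs(lfc2), abs(lfc1))
  expect_gt(lfc1, 0)

  # identical groups: exact zero by symmetry
  k0 <- rep(c(30, 50, 40), 2)
  cd0 <- count_dataset(matrix(k0, 1), info)
  cd0$size_factors <- rep(1, 6)
  fit0 <- fit_map_lfc(cd0, Xe, dispersions = 0.1, prior)
  expect_equal(sum(cvec * fit0$beta[1, ]), 0, tolerance = 1e-7)

  # flat prior: matches the MLE contrast
  wide <- manual_lfc_prior(Xe, sigma2_log2 = 1e8)
  Xs <- standard_design(~ condition, info)
  fitw <- fit_map_lfc(cd, Xe, dispersions = c(0.05, 0.05), wide)
  mle <- fit_mle_lfc(cd, Xs, dispersions = c(0.05, 0.05))
  expect_equal(sum(cvec * fitw$beta[1, ]), mle$beta[1, 2], tolerance = 1e-4)
})

test_that("pairwise contrasts are invariant to the declared base level", {
  withr::with_seed(71, {
    n <- 60; m <- 9
    mu <- exp(runif(n, 2, 6))
    eff_b <- rnorm(n, 0, 0.5); eff_c <- rnorm(n, 0, 0.5)
    mk <- function(mu_g) rnbinom(n, mu = mu_g, size = 1 / 0.1)
    counts <- cbind(mk(mu), mk(mu), mk(mu),
                    mk(mu * exp(eff_b)), mk(mu * exp(eff_b)), mk(mu * exp(eff_b)),
                    mk(mu * exp(eff_c)), mk(mu * exp(eff_c)), mk(mu * exp(eff_c)))
    run_with_levels <- function(levs) {
      info <- data.frame(g = factor(rep(c("a", "b", "c"), each = 3),
                                    levels = levs))
      cd <- estimate_size_factors(count_dataset(counts, info))
      Xs <- standard_design(~ g, info)
      dm <- estimate_dispersions(cd, Xs)
      mle <- fit_mle_lfc(cd, Xs, dm$final)
      Xe <- expanded_design(~ g, info)
      prior <- estimate_lfc_prior_width(mle$beta, Xs, Xe, info, ~ g)
      fit <- fit_map_lfc(cd, Xe, dm$final, prior)
      cvec <- contrast_vector(Xe, "g", "b", "a")
      t(vapply(which(fit$converged), function(i)
        c(sum(cvec * fit$beta[i, ]),
          sqrt(drop(t(cvec) %*% fit$covariances[[i]] %*% cvec))),
        numeric(2)))
    }
    r1 <- run_with_levels(c("a", "b", "c"))
    r2 <- run_with_levels(c("c", "b", "a"))
    expect_equal(r1, r2, tolerance = 1e-6)
  })
})

test_that("shrunken LFCs are more stable across split halves than MLEs", {
  sim <- simulate_dataset(n_genes = 300, m = 12, de_fraction = 0.3,
                          fold_changes = c(2, 3, 4), seed = 81)
  halves <- list(c(1:3, 7:9), c(4:6, 10:12))
  est <- lapply(halves, function(idx) {
    cd <- count_dataset(sim$dataset$counts[, idx],
                        sim$dataset$sample_info[idx, , drop = FALSE])
    cd <- estimate_size_factors(cd)
    Xs <- standard_design(~ condition, cd$sample_info)
    dm <- estimate_dispersions(cd, Xs)
    mle <- fit_mle_lfc(cd, Xs, dm$final)
    Xe <- expanded_design(~ condition, cd$sample_info)
    prior <- estimate_lfc_prior_width(mle$beta, Xs, Xe, cd$sample_info,
                                      ~ condition)
    map <- fit_map_lfc(cd, Xe, dm$final, prior)
    cvec <- contrast_vector(Xe, "condition", "B", "A")
    list(mle = mle$beta[, 2] / log(2),
         map = as.vector(map$beta %*% cvec) / log(2),
         ok = mle$converged & map$converged)
  })
  ok <- est[[1]]$ok & est[[2]]$ok
  rmse_mle <- sqrt(mean((est[[1]]$mle[ok] - est[[2]]$mle[ok])^2))
  rmse_map <- sqrt(mean((est[[1]]$map[ok] - est[[2]]$map[ok])^2))
  expect_lt(rmse_map, rmse_mle)
})

test_that("shrinkage strength falls with mean count at a fixed true LFC", {
  withr::with_seed(93, {
    n_per <- 200
    means <- c(5, 25, 125)
    info <- two_group_info(6)
    Xe <- expanded_design(~ condition, info)
    cvec <- contrast_vector(Xe, "condition", "B", "A")
    mean_abs <- vapply(means, function(mu) {
      counts <- t(replicate(n_per,
        rnbinom(6, mu = mu * 2^(c(0, 0, 0, 1, 1, 1) - 0.5), size = 1 / 0.02)))
      cd <- count_dataset(counts, info)
      cd$size_factors <- rep(1, 6)
      prior <- manual_lfc_prior(Xe, sigma2_log2 = 0.25)
      fit <- fit_map_lfc(cd, Xe, rep(0.02, n_per), prior)
      mean(abs(fit$beta[fit$converged, ] %*% cvec)) / log(2)
    }, numeric(1))
    expect_true(all(diff(mean_abs) > 0))
  })
})
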