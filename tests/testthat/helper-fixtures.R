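# shared fixture builders; everything is generated in code under fixed seeds

two_group_info <- function(m) {
  data.frame(condition = factor(rep(c("A", "B"), each = m / 2)),
             row.names = paste0("s", seq_len(m)))
}

# a small deterministic NB dataset with two balanced groups
make_two_group_dataset <- function(n = 100, m = 6, seed = 42, mu_range = c(5, 500),
                                   alpha = 0.1, lfc = NULL) {
  withr::with_seed(seed, {
    mu <- exp(runif(n, log(mu_range[1]), log(mu_range[2])))
    lfc <- lfc %||% rep(0, n)
    half <- 2^(lfc / 2)
    mu_mat <- cbind(matrix(rep(mu / half, m / 2), ncol = m / 2),
                    matrix(rep(mu * half, m / 2), ncol = m / 2))
    counts <- matrix(rnbinom(n * m, mu = as.vector(mu_mat), size = 1 / alpha),
                     nrow = n)
    colnames(counts) <- paste0("s", seq_len(m))
    count_dataset(counts, two_group_info(m))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force BH step-up, independent of stats::p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# plain (unadjusted) NB profile log-likelihood in the dispersion
nb_loglik_alpha <- function(alpha, counts, mu) {
  sum(dnbinom(counts, mu = mu, size = 1 / alpha, log = TRUE))
}
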