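# unseeded internal pair sampler; exported wrappers set the seed exactly once
draw_mean_dispersion <- function(n_genes, meanlog = 4, sdlog = 2,
                                 mean_floor = 0.5, a1 = 3, alpha0 = 0.05,
                                 sigma_d = 0.5) {
  stopifnot(n_genes >= 1, sdlog >= 0, mean_floor > 0, a1 >= 0, alpha0 > 0,
            sigma_d >= 0)
  means <- pmax(stats::rlnorm(n_genes, meanlog, sdlog), mean_floor)
  disp <- (a1 / means + alpha0) * exp(stats::rnorm(n_genes, 0, sigma_d))
  list(mean = means, dispersion = disp)
}

#' Draw gene means and dispersions for simulation
#'
#' Means come from a truncated log-normal (defaults: log-mean 4, log-sd 2,
#' floor 0.5), dispersions from the trend `a1/mu + alpha0` (defaults 3 and
#' 0.05, mimicking the shot-noise rise at low means and an asymptote near
#' 0.05 seen in real RNA-seq data) multiplied by log-normal noise of
#' log-scale SD `sigma_d` (default 0.5). Deterministic given `seed`.
#'
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @param meanlog,sdlog,mean_floor log-normal parameters for means.
#' @param a1,alpha0,sigma_d dispersion trend and scatter parameters.
#' @return List with `mean` and `dispersion` vectors.
#' @export
sample_mean_dispersion_pairs <- function(n_genes, seed = 1, meanlog = 4,
                                         sdlog = 2, mean_floor = 0.5,
                                         a1 = 3, alpha0 = 0.05,
                                         sigma_d = 0.5) {
  with_local_seed(seed,
    draw_mean_dispersion(n_genes, meanlog, sdlog, mean_floor, a1, alpha0,
                         sigma_d))
}

#' Simulate a two-group negative binomial dataset with known truth
#'
#' Generates `n_genes` genes over two balanced groups of `m/2` samples.
#' A fraction `de_fraction` of genes (default 20%) is differentially
#' expressed with fold changes drawn from `fold_changes` (default
#' \{2, 3, 4\}) and random direction; the fold change is split
#' symmetrically (one group's mean multiplied by `sqrt(fc)`, the other
#' divided), so the group-mean ratio equals the fold change while the
#' average expression stays at the drawn mean. Null genes share one mean.
#' Counts are NB with gene-specific dispersion.
#'
#' @param n_genes number of genes (default 10000).
#' @param m total number of samples (even, at least 4).
#' @param de_fraction fraction of truly DE genes.
#' @param fold_changes candidate fold changes (linear scale).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of it.
#' @param ... further generator parameters passed to the mean/dispersion
#'   sampler (`meanlog`, `sdlog`, `mean_floor`, `a1`, `alpha0`, `sigma_d`).
#' @return Object of class `simulated_dataset`: list with `dataset` (a
#'   [count_dataset()] whose `sample_info` has a two-level `condition`
#'   factor), `is_de`, `true_lfc` (signed log2, group B over group A),
#'   `true_dispersion`, `true_mean` and `seed`.
#' @export
simulate_dataset <- function(n_genes = 10000, m = 6, de_fraction = 0.2,
                             fold_changes = c(2, 3, 4), seed = 1, ...) {
  stopifnot(m >= 4, m %% 2 == 0, de_fraction >= 0, de_fraction <= 1,
            all(fold_changes > 1))
  with_local_seed(seed, {
    pars <- draw_mean_dispersion(n_genes, ...)
    means <- pars$mean
    disp <- pars$dispersion
    is_de <- rep(FALSE, n_genes)
    n_de <- round(de_fraction * n_genes)
    if (n_de > 0) is_de[sample.int(n_genes, n_de)] <- TRUE
    true_lfc <- rep(0, n_genes)
    if (n_de > 0) {
      fc <- fold_changes[sample.int(length(fold_changes), n_de, replace = TRUE)]
      dir <- c(-1, 1)[sample.int(2, n_de, replace = TRUE)]
      true_lfc[is_de] <- dir * log2(fc)
    }
    half <- 2^(true_lfc / 2)
    mu_a <- means / half
    mu_b <- means * half
    m2 <- m / 2
    mu_mat <- cbind(matrix(rep(mu_a, m2), ncol = m2),
                    matrix(rep(mu_b, m2), ncol = m2))
    counts <- matrix(
      stats::rnbinom(n_genes * m, mu = as.vector(mu_mat),
                     size = rep(1 / disp, m)),
      nrow = n_genes, ncol = m)
    colnames(counts) <- paste0("sample", seq_len(m))
    rownames(counts) <- paste0("gene", seq_len(n_genes))
    info <- data.frame(condition = factor(rep(c("A", "B"), each = m2)),
                       row.names = colnames(counts))
    structure(
      list(dataset = count_dataset(counts, info), is_de = is_de,
           true_lfc = true_lfc, true_dispersion = disp, true_mean = means,
           seed = seed),
      class = "simulated_dataset")
  })
}

#' Sensitivity, precision and false positive rate of a result table
#'
#' Sensitivity is the fraction of truly DE genes with adjusted p below
#' `alpha_adj`; precision is the fraction of truly DE genes among those
#' called; FDR is one minus precision; `fpr_at_0.01` is the fraction of
#' raw p-values below 0.01 among all computed tests. Genes with missing
#' adjusted p count as not called.
#'
#' @param result data.frame with columns `pvalue` and `padj` (e.g. from
#'   [run_pipeline()]), aligned with `is_de`.
#' @param is_de logical ground-truth labels.
#' @param alpha_adj adjusted-p calling threshold (default 0.1).
#' @return List with `sensitivity`, `precision`, `fdr`, `fpr_at_0.01`,
#'   `tp`, `fp`, `tn`, `fn`, `n_called`.
#' @export
evaluate_performance <- function(result, is_de, alpha_adj = 0.1) {
  if (nrow(result) != length(is_de))
    stop("result table and truth labels have different lengths")
  called <- !is.na(result$padj) & result$padj < alpha_adj
  tp <- sum(called & is_de)
  fp <- sum(called & !is_de)
  fn <- sum(!called & is_de)
  tn <- sum(!called & !is_de)
  sens <- if (sum(is_de) > 0) tp / sum(is_de) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  tested <- !is.na(result$pvalue)
  fpr <- if (any(tested)) mean(result$pvalue[tested] < 0.01) else NA_real_
  list(sensitivity = sens, precision = prec,
       fdr = if (is.na(prec)) NA_real_ else 1 - prec,
       fpr_at_0.01 = fpr, tp = tp, fp = fp, tn = tn, fn = fn,
       n_called = tp + fp)
}
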