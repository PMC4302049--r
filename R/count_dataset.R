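#' Construct a count dataset
#'
#' Bundles a non-negative integer count matrix (genes in rows, samples in
#' columns) with per-sample metadata and, once estimated, normalization
#' factors. This is the container every other function in the package
#' operates on.
#'
#' @param counts integer matrix, genes x samples, entries `K_ij >= 0`.
#' @param sample_info data.frame with one row per sample (factors and
#'   numeric covariates used in the design).
#' @param gene_ids optional character vector of row labels; defaults to
#'   `rownames(counts)` or `gene1..geneN`.
#'
#' @return An object of class `count_dataset`: a list with elements
#'   `counts`, `sample_info`, `gene_ids`, `size_factors` (NULL until
#'   [estimate_size_factors()] is run) and `norm_factors` (optional
#'   gene x sample matrix overriding per-sample factors).
#' @export
count_dataset <- function(counts, sample_info = NULL, gene_ids = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(!is_wholenumber(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "double"  # keep double to avoid integer overflow downstream
  m <- ncol(counts)
  if (is.null(sample_info)) {
    sample_info <- data.frame(row.names = colnames(counts) %||% paste0("sample", seq_len(m)))
  }
  if (nrow(sample_info) != m)
    stop("sample_info must have one row per sample (", m, " expected, got ",
         nrow(sample_info), ")")
  if (is.null(gene_ids)) {
    gene_ids <- rownames(counts) %||% paste0("gene", seq_len(nrow(counts)))
  }
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length must equal number of rows of counts")
  rownames(counts) <- gene_ids
  structure(
    list(counts = counts, sample_info = sample_info, gene_ids = gene_ids,
         size_factors = NULL, norm_factors = NULL),
    class = "count_dataset"
  )
}

#' @export
print.count_dataset <- function(x, ...) {
  cat("count_dataset:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  if (!is.null(x$size_factors))
    cat("size factors:", paste(signif(x$size_factors, 4), collapse = " "), "\n")
  if (!is.null(x$norm_factors))
    cat("gene-specific normalization factor matrix set\n")
  if (ncol(x$sample_info))
    cat("sample_info columns:", paste(names(x$sample_info), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_dataset <- function(x) dim(x$counts)

#' Median-of-ratios size factors
#'
#' Estimates per-sample normalization constants \eqn{s_j} by the
#' median-of-ratios method: each sample's counts are divided by the
#' per-gene geometric mean across samples (the pseudo-reference), and
#' \eqn{s_j} is the median of those ratios over genes whose reference is
#' non-zero, i.e. genes with all counts positive.
#'
#' @param dataset a [count_dataset()].
#' @return The dataset with `$size_factors` filled in. Use
#'   [size_factors()] to extract the numeric vector.
#' @export
estimate_size_factors <- function(dataset) {
  stopifnot(inherits(dataset, "count_dataset"))
  dataset$size_factors <- size_factors_for_matrix(dataset$counts)
  dataset
}

#' @rdname estimate_size_factors
#' @param counts a genes x samples count matrix.
#' @export
size_factors_for_matrix <- function(counts) {
  log_geo <- rowMeans(log(counts))         # -Inf for any row containing a zero
  use <- is.finite(log_geo)
  if (!any(use))
    stop("no reference genes: every gene has at least one zero count, ",
         "cannot apply the median-of-ratios estimator")
  s <- apply(counts[use, , drop = FALSE], 2, function(col) {
    stats::median(exp(log(col) - log_geo[use]))
  })
  if (any(!is.finite(s)) || any(s <= 0))
    stop("size factor estimation produced non-positive values")
  unname(s)
}

#' Accessors for normalization factors
#'
#' @param dataset a [count_dataset()].
#' @return `size_factors()` returns the per-sample vector \eqn{s_j};
#'   `normalization_matrix()` returns the full gene x sample matrix
#'   \eqn{s_ij} (recycled from `s_j` when no gene-specific factors were
#'   supplied).
#' @export
size_factors <- function(dataset) {
  stopifnot(inherits(dataset, "count_dataset"))
  dataset$size_factors
}

#' @rdname size_factors
#' @export
normalization_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "count_dataset"))
  if (!is.null(dataset$norm_factors)) return(dataset$norm_factors)
  if (is.null(dataset$size_factors))
    stop("normalization factors not set; run estimate_size_factors() first")
  matrix(dataset$size_factors, nrow = nrow(dataset$counts),
         ncol = ncol(dataset$counts), byrow = TRUE,
         dimnames = dimnames(dataset$counts))
}

#' Supply gene-specific normalization factors
#'
#' Overrides per-sample size factors with a full \eqn{s_{ij}} matrix, e.g.
#' from GC-content or gene-length correction methods.
#'
#' @param dataset a [count_dataset()].
#' @param factors positive matrix with the same shape as the counts.
#' @return The updated dataset.
#' @export
set_normalization_factors <- function(dataset, factors) {
  stopifnot(inherits(dataset, "count_dataset"))
  factors <- as.matrix(factors)
  if (!identical(dim(factors), dim(dataset$counts)))
    stop("normalization factor matrix must match the count matrix shape")
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("normalization factors must be strictly positive")
  dataset$norm_factors <- factors
  dataset
}

#' Normalized counts
#'
#' @param dataset a [count_dataset()] with normalization set.
#' @return Matrix of \eqn{K_{ij}/s_{ij}}.
#' @export
normalized_counts <- function(dataset) {
  dataset$counts / normalization_matrix(dataset)
}

#' Mean of normalized counts per gene
#'
#' The average expression strength \eqn{\bar\mu_i = m^{-1}\sum_j K_{ij}/s_{ij}},
#' used as the covariate of the dispersion trend and as the filter statistic
#' of independent filtering.
#'
#' @param dataset a [count_dataset()] with normalization set.
#' @return Numeric vector, one value per gene; 0 exactly for all-zero genes.
#' @export
mean_normalized_counts <- function(dataset) {
  rowMeans(normalized_counts(dataset))
}
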