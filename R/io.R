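#' Read a count matrix from delimited text
#'
#' Expects genes as rows with the first column holding gene IDs and one
#' column per sample. The delimiter is inferred from the file extension
#' (`.csv` = comma, otherwise tab). Counts must be non-negative integers;
#' violations are reported with their row and column.
#'
#' @param path file path.
#' @param sep optional explicit field separator.
#' @return Integer-valued numeric matrix with gene IDs as rownames.
#' @export
read_counts <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df)
  if (!is.numeric(mat)) stop("non-numeric entries in count file ", path)
  bad <- which(!is_wholenumber(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("counts must be non-negative integers; first offender in ", path,
         " at row '", rownames(mat)[bad[1, 1]], "', column '",
         colnames(mat)[bad[1, 2]], "' (value ", mat[bad[1, , drop = FALSE]], ")")
  mat
}

#' Read per-sample metadata
#'
#' One row per sample; character columns are converted to factors.
#'
#' @inheritParams read_counts
#' @return data.frame with sample IDs as rownames.
#' @export
read_sample_info <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  df
}

#' Read a count matrix in MatrixMarket triplet format
#'
#' @param mtx_path path to the `.mtx` file.
#' @param genes_path text file with one gene ID per line (rows).
#' @param samples_path text file with one sample ID per line (columns).
#' @return Dense integer-valued matrix.
#' @export
read_counts_mtx <- function(mtx_path, genes_path, samples_path) {
  mat <- as.matrix(Matrix::readMM(mtx_path))
  genes <- readLines(genes_path)
  samples <- readLines(samples_path)
  if (length(genes) != nrow(mat) || length(samples) != ncol(mat))
    stop("label files do not match matrix dimensions")
  dimnames(mat) <- list(genes, samples)
  if (any(!is_wholenumber(mat) | mat < 0))
    stop("counts must be non-negative integers in ", mtx_path)
  mat
}

#' Write a result table as TSV
#'
#' Columns in fixed order (`baseMean`, `log2FoldChange`, `lfcSE`, `stat`,
#' `pvalue`, `padj`, `maxCooks`, `status`) preceded by a `gene` ID column;
#' missing values are rendered as `NA`.
#'
#' @param table result data.frame from [run_pipeline()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_results <- function(table, path) {
  cols <- c("baseMean", "log2FoldChange", "lfcSE", "stat", "pvalue",
            "padj", "maxCooks", "status")
  cols <- intersect(cols, colnames(table))
  out <- data.frame(gene = rownames(table), table[, cols, drop = FALSE],
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a matrix (e.g. rlog values or simulated counts) as TSV
#'
#' @param mat numeric matrix with row and column names.
#' @param path output file path.
#' @param id_column header for the first (rowname) column.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_column = "gene") {
  out <- data.frame(rownames(mat) %||% seq_len(nrow(mat)), mat,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out)[1] <- id_column
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
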