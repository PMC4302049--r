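#' Standard design matrix from a formula
#'
#' Thin wrapper over [stats::model.matrix()] producing the full-rank,
#' base-level design used for dispersion estimation, for estimating the
#' width of the LFC prior, and for maximum-likelihood fits.
#'
#' @param formula a one-sided formula over columns of `sample_info`, e.g.
#'   `~ condition` or `~ batch + condition` or
#'   `~ genotype + treatment + genotype:treatment`.
#' @param sample_info data.frame of per-sample covariates.
#' @return Numeric design matrix with an attached `"formula"` attribute.
#' @export
standard_design <- function(formula, sample_info) {
  sample_info <- check_factor_levels(formula, sample_info)
  X <- stats::model.matrix(formula, data = sample_info)
  attr(X, "formula") <- formula
  attr(X, "assign") <- attr(stats::model.matrix(formula, data = sample_info), "assign")
  X
}

check_factor_levels <- function(formula, sample_info) {
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(sample_info))
  if (length(missing_vars))
    stop("design variables not found in sample_info: ",
         paste(missing_vars, collapse = ", "))
  for (v in vars) {
    if (is.character(sample_info[[v]])) sample_info[[v]] <- factor(sample_info[[v]])
    if (is.factor(sample_info[[v]])) {
      tab <- table(sample_info[[v]])
      if (any(tab == 0))
        stop("factor '", v, "' has a level with zero samples")
      if (nlevels(sample_info[[v]]) < 2)
        stop("factor '", v, "' has fewer than two levels")
    }
  }
  sample_info
}

design_factors <- function(formula, sample_info) {
  vars <- all.vars(formula)
  vars[vapply(vars, function(v)
    is.factor(sample_info[[v]]) || is.character(sample_info[[v]]), logical(1))]
}

has_interactions <- function(formula) {
  any(attr(stats::terms(formula), "order") > 1)
}

#' Expanded (over-parameterized) design matrix
#'
#' Builds a design with an intercept column plus one indicator column for
#' every level of every factor (no level is absorbed into the intercept),
#' plus any numeric covariate and interaction columns. The matrix is rank
#' deficient by construction; ridge shrinkage with a positive penalty on
#' all non-intercept columns makes the fit unique, and symmetric across
#' factor levels, so contrasts do not depend on which level is declared
#' first.
#'
#' Exception: when the design contains interaction terms and all factors
#' have exactly two levels, a standard full-rank design is returned
#' instead, so that a single coefficient tests departure from additivity.
#'
#' @inheritParams standard_design
#' @return Numeric design matrix with attributes: `"factor_columns"` (named
#'   list mapping each factor to its indicator column indices),
#'   `"expanded"` (logical), `"interactions"` (logical).
#' @export
expanded_design <- function(formula, sample_info) {
  sample_info <- check_factor_levels(formula, sample_info)
  facs <- design_factors(formula, sample_info)
  inter <- has_interactions(formula)
  all_two_level <- length(facs) > 0 &&
    all(vapply(facs, function(v) nlevels(factor(sample_info[[v]])) == 2L, logical(1)))
  if (inter && all_two_level) {
    X <- standard_design(formula, sample_info)
    attr(X, "expanded") <- FALSE
    attr(X, "interactions") <- TRUE
    attr(X, "factor_columns") <- standard_factor_columns(X, formula, sample_info)
    return(X)
  }
  m <- nrow(sample_info)
  cols <- list("(Intercept)" = rep(1, m))
  factor_columns <- list()
  for (v in facs) {
    f <- factor(sample_info[[v]])
    idx <- integer(0)
    for (lev in levels(f)) {
      nm <- paste0(v, lev)
      cols[[nm]] <- as.numeric(f == lev)
      idx <- c(idx, length(cols))
    }
    factor_columns[[v]] <- idx
  }
  covs <- setdiff(all.vars(formula), facs)
  for (v in covs) cols[[v]] <- as.numeric(sample_info[[v]])
  if (inter) {
    # interaction columns between expanded indicators of the involved terms
    tl <- attr(stats::terms(formula), "term.labels")
    for (term in tl[grepl(":", tl, fixed = TRUE)]) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      part_cols <- lapply(parts, function(p) {
        if (p %in% facs) {
          f <- factor(sample_info[[p]])
          stats::setNames(lapply(levels(f), function(l) as.numeric(f == l)),
                          paste0(p, levels(f)))
        } else stats::setNames(list(as.numeric(sample_info[[p]])), p)
      })
      grid <- expand.grid(lapply(part_cols, names), stringsAsFactors = FALSE)
      for (g in seq_len(nrow(grid))) {
        nm <- paste(unlist(grid[g, ]), collapse = ".")
        val <- Reduce(`*`, Map(function(pc, name) pc[[name]], part_cols, unlist(grid[g, ])))
        cols[[nm]] <- val
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "formula") <- formula
  attr(X, "expanded") <- TRUE
  attr(X, "interactions") <- inter
  attr(X, "factor_columns") <- factor_columns
  X
}

# map factors to their non-base indicator columns in a standard design
standard_factor_columns <- function(X, formula, sample_info) {
  facs <- design_factors(formula, sample_info)
  out <- list()
  for (v in facs) {
    levs <- levels(factor(sample_info[[v]]))
    out[[v]] <- which(colnames(X) %in% paste0(v, levs))
  }
  out
}

#' Contrast vector for a pairwise level comparison
#'
#' Returns the numeric contrast extracting the log2 fold change of
#' `level_num` versus `level_den` of `factor` from a fitted coefficient
#' vector on the given design.
#'
#' @param design matrix from [standard_design()] or [expanded_design()].
#' @param factor_name name of the factor.
#' @param level_num,level_den numerator and denominator levels.
#' @return Numeric vector of length `ncol(design)`.
#' @export
contrast_vector <- function(design, factor_name, level_num, level_den) {
  cn <- colnames(design)
  cvec <- numeric(ncol(design))
  names(cvec) <- cn
  nm_num <- paste0(factor_name, level_num)
  nm_den <- paste0(factor_name, level_den)
  if (isTRUE(attr(design, "expanded"))) {
    if (!(nm_num %in% cn) || !(nm_den %in% cn))
      stop("levels not found in expanded design: ", nm_num, " / ", nm_den)
    cvec[nm_num] <- 1
    cvec[nm_den] <- -1
  } else {
    # base level columns are absent: a missing column contributes zero
    if (nm_num %in% cn) cvec[nm_num] <- 1
    else if (nm_den %in% cn) { } # handled below
    if (nm_den %in% cn) cvec[nm_den] <- cvec[nm_den] - 1
    if (all(cvec == 0))
      stop("contrast ", level_num, " vs ", level_den,
           " not expressible in this design")
  }
  cvec
}
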