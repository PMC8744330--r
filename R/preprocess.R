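#' Filter lowly expressed genes by CPM
#'
#' A gene is retained iff its log2(CPM) exceeds `log2cpm_threshold` in
#' strictly more than `sample_fraction` of the samples. CPM uses the raw
#' library sizes (no normalization factors), so filtering is independent of
#' TMM.
#'
#' @param counts Gene x sample count matrix (nonnegative).
#' @param log2cpm_threshold Expression threshold on the log2 CPM scale
#'   (default 1).
#' @param sample_fraction Required fraction of samples, exceeded strictly
#'   (default 0.25).
#' @return Character vector of retained gene names (or integer indices when
#'   `counts` has no rownames).
#' @export
filter_genes <- function(counts, log2cpm_threshold = 1, sample_fraction = 0.25) {
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("all-zero sample(s): ", paste(which(lib == 0), collapse = ", "))
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  ok <- rowMeans(log2(cpm) > log2cpm_threshold) > sample_fraction
  if (is.null(rownames(counts))) which(ok) else rownames(counts)[ok]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors (trim 30% on M, 5% on A,
#' precision-weighted mean of M against the reference sample whose
#' upper-quartile count fraction is closest to the mean), normalized so the
#' factors' log-mean is zero. Computed by edgeR.
#'
#' @param counts Gene x sample count matrix.
#' @return Named numeric vector of per-sample scaling factors.
#' @export
tmm_factors <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with zero library size: ", paste(which(lib == 0), collapse = ", "))
  }
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  setNames(as.numeric(f), colnames(counts))
}

#' Log2 CPM with TMM-effective library sizes
#'
#' `log2(count / (library_size * factor) * 1e6 + pseudocount)`; the default
#' pseudocount of 1 is on the CPM scale, so a zero count maps to
#' `log2(pseudocount)`.
#'
#' @param counts Gene x sample count matrix.
#' @param factors Per-sample scaling factors (e.g. [tmm_factors()]).
#' @param pseudocount Added on the CPM scale before log2 (default 1).
#' @return Gene x sample matrix of log2 expression.
#' @export
normalize_log2 <- function(counts, factors, pseudocount = 1) {
  stopifnot(all(factors > 0), length(factors) == ncol(counts))
  eff <- colSums(counts) * factors
  log2(sweep(counts, 2, eff, "/") * 1e6 + pseudocount)
}

#' Residualize expression against sample covariates
#'
#' Fits per-gene ordinary least squares of expression on the covariates
#' (categoricals one-hot with the reference level dropped) and returns the
#' residual matrix. Two network sets are supported from one code path: with
#' and without age in the design (`include_age`).
#'
#' @param expr Gene x sample matrix (e.g. from [normalize_log2()]).
#' @param covars Tibble/data.frame with one row per sample: `site`, `rin`,
#'   `ischemic_time`, `exonic_rate`, `rrna_rate`, `intergenic_rate`, `sex`,
#'   `age` (decade midpoint). Extra columns (e.g. `sample_id`) are ignored.
#' @param include_age Also regress out age? Default `FALSE` (age-signal
#'   preserving), matching the network set used for age correlation.
#' @return Gene x sample matrix of residuals with attributes
#'   `tmm_applied = NA`, `covariates_adjusted = TRUE`, `age_adjusted`.
#' @export
adjust_covariates <- function(expr, covars, include_age = FALSE) {
  covars <- as.data.frame(covars)
  wanted <- c("site", "rin", "ischemic_time", "exonic_rate", "rrna_rate",
              "intergenic_rate", "sex")
  if (include_age) wanted <- c(wanted, "age")
  missing_cols <- setdiff(wanted, colnames(covars))
  if (length(missing_cols)) {
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(covars) != ncol(expr)) stop("covars rows must match expr columns")
  if (anyNA(covars[wanted])) stop("missing covariate values are not allowed")
  df <- covars[wanted]
  for (cc in c("site", "sex")) df[[cc]] <- factor(df[[cc]])
  # single-level factors carry no information; drop them rather than fail
  keep <- vapply(df, function(x) !is.factor(x) || nlevels(droplevels(x)) > 1, logical(1))
  df <- df[keep]
  design <- model.matrix(~ ., data = df)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- lm.fit(design, t(expr))
  res <- t(fit$residuals)
  dimnames(res) <- dimnames(expr)
  structure(res, covariates_adjusted = TRUE, age_adjusted = include_age)
}

#' One-call preprocessing of a tissue's counts
#'
#' Filter genes, compute TMM factors, log2-transform and residualize, i.e.
#' the full path from raw counts to the expression used for network
#' construction and age correlation.
#'
#' @inheritParams adjust_covariates
#' @param counts Gene x sample raw count matrix.
#' @param log2cpm_threshold,sample_fraction Passed to [filter_genes()].
#' @param pseudocount Passed to [normalize_log2()].
#' @return Residual matrix as in [adjust_covariates()], restricted to
#'   retained genes, with attribute `tmm_applied = TRUE`.
#' @export
preprocess_tissue <- function(counts, covars, include_age = FALSE,
                              log2cpm_threshold = 1, sample_fraction = 0.25,
                              pseudocount = 1) {
  keep <- filter_genes(counts, log2cpm_threshold, sample_fraction)
  counts <- counts[keep, , drop = FALSE]
  f <- tmm_factors(counts)
  le <- normalize_log2(counts, f, pseudocount)
  out <- adjust_covariates(le, covars, include_age = include_age)
  attr(out, "tmm_applied") <- TRUE
  out
}
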