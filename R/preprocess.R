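# QC, median-of-ratios normalization, log2 transform, covariate residualization.

#' Filter low-information genes and shallow samples from a count table
#'
#' Retains genes observed at `>= min_gene_count` in at least
#' `min_gene_samples` samples, and samples whose total count is at least
#' `min_sample_total`. Both rules are evaluated on the input matrix, and the
#' input ordering of surviving genes and samples is preserved.
#'
#' @param counts Expression table at stage `raw_counts` (see
#'   [expression_table()]).
#' @param min_gene_count,min_gene_samples,min_sample_total QC thresholds.
#'   Defaults are deliberately conservative placeholders; real analyses should
#'   set them to match the sequencing depth at hand.
#' @return A filtered expression table at stage `raw_counts`.
#' @export
qc_filter <- function(counts, min_gene_count = 5, min_gene_samples = 10,
                      min_sample_total = 1e5) {
  check_stage(counts, "raw_counts", "qc_filter()")
  m <- expr_values(counts)
  keep_g <- rowSums(m >= min_gene_count) >= min_gene_samples
  keep_s <- colSums(m) >= min_sample_total
  if (!any(keep_g) || !any(keep_s)) {
    stop_nephronet("QC removed every gene or every sample; relax the thresholds",
                   "nephronet_degenerate_error")
  }
  expression_table(m[keep_g, keep_s, drop = FALSE], "raw_counts")
}

#' Median-of-ratios size factors
#'
#' For each sample j the size factor is the median over reference genes of
#' `count[g, j] / geomean_g`, where `geomean_g` is gene g's geometric mean
#' across samples and the reference set is the genes with strictly positive
#' counts in every sample (the DESeq convention).
#'
#' @param counts Expression table at stage `raw_counts`.
#' @return A tibble with columns `sample_id` and `size_factor` (> 0).
#' @export
median_of_ratios <- function(counts) {
  check_stage(counts, "raw_counts", "median_of_ratios()")
  m <- expr_values(counts)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    stop_nephronet(
      "no gene has positive counts in every sample; median-of-ratios is infeasible",
      "nephronet_normalization_error")
  }
  log_geo <- rowMeans(log(m[ref, , drop = FALSE]))
  factors <- apply(log(m[ref, , drop = FALSE]) - log_geo, 2,
                   function(lr) exp(median(lr)))
  tibble(sample_id = colnames(m), size_factor = unname(factors))
}

#' Divide by size factors and log2-transform
#'
#' `value'[g, j] = log2(value[g, j] / size_factor_j + pseudocount)`.
#'
#' @param counts Expression table at stage `raw_counts`.
#' @param factors Size-factor tibble from [median_of_ratios()]; must cover all
#'   samples of `counts`.
#' @param pseudocount Added before the log; the default 1 keeps zeros at zero.
#' @return An expression table at stage `normalized`.
#' @export
normalize_log <- function(counts, factors, pseudocount = 1) {
  check_stage(counts, "raw_counts", "normalize_log()")
  m <- expr_values(counts)
  if (!all(colnames(m) %in% factors$sample_id)) {
    missing <- setdiff(colnames(m), factors$sample_id)
    stop_nephronet(sprintf("no size factor for sample(s): %s",
                           paste(head(missing, 5), collapse = ", ")),
                   "nephronet_alignment_error")
  }
  f <- setNames(factors$size_factor, factors$sample_id)[colnames(m)]
  if (any(f <= 0)) {
    stop_nephronet("size factors must be positive", "nephronet_alignment_error")
  }
  out <- log2(sweep(m, 2, f, "/") + pseudocount)
  expression_table(out, "normalized")
}

#' Residualize expression on sample covariates
#'
#' Each gene's normalized expression is replaced by the residuals of an
#' ordinary least-squares fit on an intercept plus every covariate column, so
#' per-gene residual means are zero and linear covariate effects (batch,
#' technical axes) are removed before decomposition.
#'
#' @param expr Expression table at stage `normalized`.
#' @param covariates Tibble with `sample_id` plus numeric covariate columns,
#'   covering every sample in `expr`.
#' @return An expression table at stage `log_corrected`.
#' @export
correct_covariates <- function(expr, covariates) {
  check_stage(expr, "normalized", "correct_covariates()")
  m <- expr_values(expr)
  if (!all(colnames(m) %in% covariates$sample_id)) {
    missing <- setdiff(colnames(m), covariates$sample_id)
    stop_nephronet(sprintf("covariates missing for sample(s): %s",
                           paste(head(missing, 5), collapse = ", ")),
                   "nephronet_alignment_error")
  }
  cov <- covariates[match(colnames(m), covariates$sample_id), , drop = FALSE]
  covm <- as.matrix(cov[, setdiff(names(cov), "sample_id"), drop = FALSE])
  if (ncol(covm) > 0 && !is.numeric(covm)) {
    stop_nephronet("covariates must be numerically encoded", "nephronet_format_error")
  }
  # constant columns duplicate the intercept; drop them rather than flag
  # collinearity so an intercept-equivalent covariate reduces to centering
  if (ncol(covm) > 0) {
    constant <- apply(covm, 2, function(x) sd(x) == 0)
    covm <- covm[, !constant, drop = FALSE]
  }
  design <- cbind(`(Intercept)` = 1, covm)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop_nephronet(sprintf("covariate matrix is rank-deficient; collinear column(s): %s",
                           paste(dropped, collapse = ", ")),
                   "nephronet_collinearity_error")
  }
  resid <- t(qr.resid(qr_d, t(m)))
  dimnames(resid) <- dimnames(m)
  expression_table(resid, "log_corrected")
}

#' Run the full preprocessing chain on one compendium
#'
#' Convenience wrapper: [qc_filter()] (optional), [median_of_ratios()],
#' [normalize_log()], then [correct_covariates()] when covariates are given.
#'
#' @inheritParams qc_filter
#' @inheritParams normalize_log
#' @param covariates Optional covariate tibble; `NULL` skips residualization
#'   (output is then mean-centered per gene so downstream standardization sees
#'   the same contract).
#' @return An expression table at stage `log_corrected`.
#' @export
preprocess_counts <- function(counts, covariates = NULL, min_gene_count = 5,
                              min_gene_samples = 10, min_sample_total = 0,
                              pseudocount = 1) {
  filtered <- qc_filter(counts, min_gene_count, min_gene_samples, min_sample_total)
  normalized <- normalize_log(filtered, median_of_ratios(filtered), pseudocount)
  if (is.null(covariates)) {
    covariates <- tibble(sample_id = names(normalized)[-1])
  }
  correct_covariates(normalized, covariates)
}
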