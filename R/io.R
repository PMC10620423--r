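# Plain-text IO: TSV matrices (first column gene ID, header = sample IDs,
# tab-separated, no quoting), covariate TSVs, eigenvector TSVs with a sidecar
# JSON, and prediction grids with a sidecar JSON of null parameters.

#' Read a gene-by-sample count matrix from TSV
#'
#' @param path TSV with first column `gene_id` (any name is accepted for the
#'   first column) and one column per sample.
#' @param stage Stage to stamp on the result (`"raw_counts"` by default).
#' @return An expression table (see [expression_table()]).
#' @export
read_counts <- function(path, stage = "raw_counts") {
  if (!file.exists(path)) {
    stop_nephronet(sprintf("counts file not found: %s", path), "nephronet_io_error")
  }
  header <- names(readr::read_tsv(path, n_max = 0, show_col_types = FALSE))
  spec <- readr::cols(.default = "d")
  spec$cols[[header[1]]] <- readr::col_character()
  tbl <- readr::read_tsv(path, col_types = spec, progress = FALSE)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl[[1]]
  expression_table(m, stage)
}

#' Write an expression table to TSV
#'
#' @param expr An expression table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(expr, path) {
  readr::write_tsv(as_tibble(as.data.frame(expr)), path)
  invisible(path)
}

#' Read a sample covariate table from TSV
#'
#' @param path TSV with first column `sample_id` plus numeric covariates.
#' @return A tibble.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) {
    stop_nephronet(sprintf("covariates file not found: %s", path), "nephronet_io_error")
  }
  tbl <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  names(tbl)[1] <- "sample_id"
  tbl$sample_id <- as.character(tbl$sample_id)
  tbl
}

#' Write / read eigenvector loadings (TSV + sidecar JSON)
#'
#' The TSV holds gene IDs and one column per component; the sidecar
#' `<path>.json` stores singular values and the source label.
#'
#' @param eig An `eigenvector_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly (`read_eigenvectors()` returns the object).
#' @export
write_eigenvectors <- function(eig, path) {
  stopifnot(inherits(eig, "eigenvector_matrix"))
  tbl <- bind_cols(tibble(gene_id = rownames(eig$loadings)),
                   as_tibble(eig$loadings))
  readr::write_tsv(tbl, path)
  jsonlite::write_json(
    list(singular_values = eig$singular_values, total_ss = eig$total_ss,
         source_label = eig$source_label),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eigenvectors
#' @export
read_eigenvectors <- function(path) {
  tbl <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- as.character(tbl[[1]])
  structure(list(loadings = m, singular_values = meta$singular_values,
                 total_ss = meta$total_ss, source_label = meta$source_label),
            class = "eigenvector_matrix")
}

#' Write / read a prediction matrix (z grid TSV + sidecar JSON)
#'
#' The TSV is the gene x term z-score grid; the sidecar `<path>.json` stores
#' the log-odds grid, per-term null parameters, and skipped terms.
#'
#' @param pred A [predict_terms()] result.
#' @param path Output TSV path.
#' @return `path` invisibly (`read_predictions()` returns a
#'   `prediction_matrix`; note the annotation set is not serialized and reads
#'   back as `NULL`, so pass annotations explicitly to [evaluate_network()]).
#' @export
write_predictions <- function(pred, path) {
  stopifnot(inherits(pred, "prediction_matrix"))
  tbl <- bind_cols(tibble(gene_id = rownames(pred$z)), as_tibble(pred$z))
  readr::write_tsv(tbl, path)
  jsonlite::write_json(
    list(null_params = pred$null_params, skipped_terms = pred$skipped_terms,
         ridge_penalty = pred$ridge_penalty,
         log_odds = as.data.frame(pred$log_odds)),
    paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  tbl <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  z <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(z) <- as.character(tbl[[1]])
  lo <- as.matrix(meta$log_odds)
  rownames(lo) <- rownames(z)
  structure(list(z = z, log_odds = lo,
                 null_params = as_tibble(meta$null_params),
                 annotations = NULL,
                 skipped_terms = as.character(meta$skipped_terms %||% character()),
                 ridge_penalty = meta$ridge_penalty),
            class = "prediction_matrix")
}
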