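# broom-style tidiers.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an eigenvector matrix into a long tibble
#'
#' @param x An `eigenvector_matrix`.
#' @param ... Unused.
#' @return Tibble `gene_id`, `component`, `loading`.
#' @method tidy eigenvector_matrix
#' @export
tidy.eigenvector_matrix <- function(x, ...) {
  bind_cols(tibble(gene_id = rownames(x$loadings)), as_tibble(x$loadings)) |>
    tidyr::pivot_longer(-"gene_id", names_to = "component", values_to = "loading")
}

#' @rdname tidy.eigenvector_matrix
#' @method glance eigenvector_matrix
#' @export
glance.eigenvector_matrix <- function(x, ...) {
  tibble(source_label = x$source_label, n_genes = nrow(x$loadings),
         n_components = ncol(x$loadings),
         variance_fraction = sum(x$singular_values^2) / x$total_ss)
}

#' Tidy merged components
#'
#' @param x A `merged_components`.
#' @param ... Unused.
#' @return Tibble `gene_id`, `component`, `block`, `loading`.
#' @method tidy merged_components
#' @export
tidy.merged_components <- function(x, ...) {
  blocks <- setNames(x$block_labels, colnames(x$loadings))
  bind_cols(tibble(gene_id = rownames(x$loadings)), as_tibble(x$loadings)) |>
    tidyr::pivot_longer(-"gene_id", names_to = "component", values_to = "loading") |>
    mutate(block = unname(blocks[.data$component]),
           .after = "component")
}

#' Tidy a fitted phenotype model (one row per coefficient)
#'
#' @param x A `phenotype_model`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` (intercept first).
#' @method tidy phenotype_model
#' @export
tidy.phenotype_model <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$coefficients)),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname tidy.phenotype_model
#' @method glance phenotype_model
#' @export
glance.phenotype_model <- function(x, ...) {
  tibble(term_id = x$term_id, n_positives = x$n_positives,
         n_components = length(x$coefficients), ridge_penalty = x$ridge_penalty,
         converged = x$converged, n_iter = x$n_iter)
}

#' Tidy a prediction matrix into gene-term rows
#'
#' @param x A `prediction_matrix`.
#' @param ... Unused.
#' @return Tibble `gene_id`, `term_id`, `log_odds`, `z`.
#' @method tidy prediction_matrix
#' @export
tidy.prediction_matrix <- function(x, ...) {
  lo <- bind_cols(tibble(gene_id = rownames(x$log_odds)), as_tibble(x$log_odds)) |>
    tidyr::pivot_longer(-"gene_id", names_to = "term_id", values_to = "log_odds")
  z <- bind_cols(tibble(gene_id = rownames(x$z)), as_tibble(x$z)) |>
    tidyr::pivot_longer(-"gene_id", names_to = "term_id", values_to = "z")
  left_join(lo, z, by = c("gene_id", "term_id"))
}

#' @rdname tidy.prediction_matrix
#' @method glance prediction_matrix
#' @export
glance.prediction_matrix <- function(x, ...) {
  tibble(n_genes = nrow(x$log_odds), n_terms = ncol(x$log_odds),
         n_skipped_terms = length(x$skipped_terms),
         ridge_penalty = x$ridge_penalty)
}

#' Tidy a network comparison (per-term rows)
#'
#' @param x A `network_comparison`.
#' @param ... Unused.
#' @return The per-term tibble (`term_id`, `auc_a`, `auc_b`, `delong_p`,
#'   `better`); `glance()` returns the group summary tibble.
#' @method tidy network_comparison
#' @export
tidy.network_comparison <- function(x, ...) x$terms

#' @rdname tidy.network_comparison
#' @method glance network_comparison
#' @export
glance.network_comparison <- function(x, ...) x$groups

#' Tidy a candidate list
#'
#' @param x A `candidate_list`.
#' @param ... Unused.
#' @return The ranking tibble.
#' @method tidy candidate_list
#' @export
tidy.candidate_list <- function(x, ...) x$ranking

#' @rdname tidy.candidate_list
#' @method glance candidate_list
#' @export
glance.candidate_list <- function(x, ...) {
  tibble(case_id = x$case_id, n_terms_used = length(x$terms_used),
         n_dropped_terms = length(x$dropped_terms),
         n_z_pass = nrow(x$ranking), n_candidates = sum(x$ranking$candidate),
         cutoff = x$cutoff, af_max = x$af_max, score_min = x$score_min)
}
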