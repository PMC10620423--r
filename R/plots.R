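# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_density
#'   geom_abline geom_vline geom_col labs theme_minimal facet_wrap coord_flip
NULL

#' @export
ggplot2::autoplot

#' Scree plot of an eigenvector decomposition
#'
#' @param eig An `eigenvector_matrix`.
#' @return A ggplot: singular value against component index.
#' @export
plot_scree <- function(eig) {
  stopifnot(inherits(eig, "eigenvector_matrix"))
  df <- tibble(component = seq_along(eig$singular_values),
               singular_value = eig$singular_values)
  ggplot(df, aes(x = .data$component, y = .data$singular_value)) +
    geom_line() + geom_point() +
    labs(title = paste("Scree:", eig$source_label),
         x = "component", y = "singular value") +
    theme_minimal()
}

#' Density of prediction z-scores, annotated vs unannotated genes
#'
#' Mirrors the usual per-phenotype diagnostic: annotated genes should sit to
#' the right of the unannotated bulk when a term is well predicted.
#'
#' @param object A `prediction_matrix`.
#' @param terms Term IDs to show (default: all, faceted).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prediction_matrix
#' @export
autoplot.prediction_matrix <- function(object, terms = NULL, ...) {
  df <- tidy(object)
  if (!is.null(terms)) df <- filter(df, .data$term_id %in% terms)
  if (!is.null(object$annotations)) {
    amat <- annotation_matrix(object$annotations, genes = rownames(object$z))
    ann <- as_tibble(as.data.frame.table(amat, responseName = "annotated",
                                         stringsAsFactors = FALSE)) |>
      rename(gene_id = "Var1", term_id = "Var2")
    df <- left_join(df, ann, by = c("gene_id", "term_id")) |>
      mutate(annotated = ifelse(.data$annotated == 1, "annotated", "unannotated"))
  } else {
    df$annotated <- "gene"
  }
  ggplot(df, aes(x = .data$z, colour = .data$annotated)) +
    geom_density() +
    facet_wrap(~term_id, scales = "free") +
    labs(x = "prediction z-score", colour = NULL) +
    theme_minimal()
}

#' Paired AUC scatter for a network comparison
#'
#' @param object A `network_comparison`.
#' @param ... Unused.
#' @return A ggplot of per-term AUCs (network B vs network A), colored by
#'   which network is significantly better; the diagonal marks parity.
#' @method autoplot network_comparison
#' @export
autoplot.network_comparison <- function(object, ...) {
  ggplot(object$terms, aes(x = .data$auc_a, y = .data$auc_b,
                           colour = .data$better)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point() +
    labs(x = "AUC, network A", y = "AUC, network B", colour = "better") +
    theme_minimal()
}

#' Candidate-gene lollipop for one patient
#'
#' @param object A `candidate_list`.
#' @param ... Unused.
#' @return A ggplot of combined z per gene, variant-filter pass highlighted,
#'   with the candidate cutoff marked.
#' @method autoplot candidate_list
#' @export
autoplot.candidate_list <- function(object, ...) {
  df <- mutate(object$ranking,
               gene_id = factor(.data$gene_id, levels = rev(.data$gene_id)))
  ggplot(df, aes(x = .data$gene_id, y = .data$combined_z,
                 fill = .data$passed_variant_filter)) +
    geom_col() +
    geom_vline(xintercept = 0) +
    coord_flip() +
    labs(title = paste("Case", object$case_id),
         x = NULL, y = "combined z", fill = "variant filter") +
    theme_minimal()
}
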