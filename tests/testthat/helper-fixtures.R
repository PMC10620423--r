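# Shared fixtures, all generated in code.

# Random gene x K loading matrix with orthonormal columns (a synthetic
# eigenvector block) -- enough structure for merge/score tests without
# running a decomposition.
random_loadings <- function(n_genes, k, seed = 1, gene_ids = NULL) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(n_genes * k), n_genes, k)))
  dimnames(q) <- list(gene_ids %||% sprintf("G%05d", seq_len(n_genes)),
                      paste0("C", seq_len(k)))
  q
}

make_eigenvectors <- function(loadings, label = "test") {
  structure(list(loadings = loadings,
                 singular_values = rev(sort(runif(ncol(loadings), 1, 10))),
                 total_ss = ncol(loadings) * 10,
                 source_label = label),
            class = "eigenvector_matrix")
}

make_merged <- function(loadings, label = "test") {
  structure(list(loadings = loadings,
                 block_labels = rep(label, ncol(loadings)),
                 sources = label),
            class = "merged_components")
}

# A synthetic prediction matrix from explicit z / log-odds grids.
make_predictions <- function(z, log_odds = z, annotations = NULL) {
  structure(list(z = z, log_odds = log_odds,
                 null_params = tibble::tibble(term_id = colnames(z)),
                 annotations = annotations, skipped_terms = character(),
                 ridge_penalty = 1),
            class = "prediction_matrix")
}

# Small end-to-end study -> merged components + annotations, for tests that
# need real pipeline objects but not the default scale.
small_pipeline <- function(seed = 1, n_genes = 250, k = 6, n_terms = 5,
                           loading_strength = 2, annotation_noise = 0.1,
                           n_permutations = 0) {
  study <- simulate_study(sim_config(
    n_genes = n_genes, n_samples_base = 40, n_samples_tissue = 30,
    n_modules = 5, module_size = min(30, n_genes %/% 5), n_terms = n_terms,
    positives_per_term = 12, loading_strength = loading_strength,
    annotation_noise = annotation_noise, seed = seed))
  pb <- preprocess_counts(study$base_counts, study$covariates_base,
                          min_sample_total = 0)
  pt <- preprocess_counts(study$tissue_counts, study$covariates_tissue,
                          min_sample_total = 0)
  mc <- merge_components(compute_components(pb, k, "base"),
                         compute_components(pt, k, "tissue"))
  pred <- predict_terms(mc, study$annotations, n_permutations = n_permutations,
                        seed = seed)
  list(study = study, components = mc, predictions = pred)
}

expect_tbl_equal <- function(a, b, ...) {
  expect_equal(as.data.frame(a), as.data.frame(b), ...)
}
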