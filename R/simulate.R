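# Synthetic multi-compendium studies with planted co-expression modules.
#
# The generator emulates the statistical structure the prediction method
# relies on: groups of disease genes that are strongly co-expressed (shared
# latent factors), a large "base" multi-tissue compendium plus a smaller
# tissue-specific compendium in which some modules are only active, library
# size heterogeneity for the normalization stage to correct, one batch
# covariate for the residualization stage, and ontology-style annotation
# files that link phenotype terms to module genes with label noise.

#' Configuration for a simulated two-compendium study
#'
#' Defaults describe a desk-scale analog of the real setting: a baseline
#' multi-tissue compendium, a smaller tissue compendium, five co-expression
#' modules of 50 genes of which two are tissue-specific, strong module
#' loadings, negative-binomial counts with bulk-RNA-seq-like overdispersion,
#' and one phenotype term per module with 10% annotation noise.
#'
#' @param n_genes Number of genes.
#' @param n_samples_base,n_samples_tissue Samples in the base (multi-tissue
#'   analog) and tissue compendium.
#' @param n_latent_factors Dense background latent factors shared by all genes.
#' @param n_modules Number of planted co-expression modules.
#' @param module_size Genes per module (`n_modules * module_size <= n_genes`).
#' @param tissue_specific_modules Integer indices of modules expressed only in
#'   the tissue compendium (zero loading in the base compendium). `NULL`
#'   (default) marks the last two modules tissue-specific (the last one if
#'   only one module is requested).
#' @param loading_strength Loading of module genes on their module factor, on
#'   the natural-log expression scale (factor scores are standard normal).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2), shared by all genes.
#' @param mean_log_expression Mean of per-gene baseline log expression.
#' @param library_size_sigma SD of log-normal per-sample size factors.
#' @param batch_effect Additive log-scale shift for the second batch level.
#' @param annotation_noise Fraction of each term's positive genes replaced by
#'   random background genes.
#' @param n_terms Number of phenotype terms (assigned to modules round-robin).
#' @param positives_per_term Annotated genes per term (<= `module_size`).
#' @param seed Integer seed; the whole study is deterministic given it.
#' @return A `sim_config` list, validated.
#' @seealso [simulate_study()]
#' @export
sim_config <- function(n_genes = 2000,
                       n_samples_base = 200,
                       n_samples_tissue = 100,
                       n_latent_factors = 10,
                       n_modules = 5,
                       module_size = 50,
                       tissue_specific_modules = NULL,
                       loading_strength = 2,
                       nb_dispersion = 0.1,
                       mean_log_expression = 4,
                       library_size_sigma = 0.3,
                       batch_effect = 0.5,
                       annotation_noise = 0.1,
                       n_terms = 5,
                       positives_per_term = 20,
                       seed = 1) {
  if (is.null(tissue_specific_modules)) {
    tissue_specific_modules <- unique(max(1L, n_modules - 1L):n_modules)
  }
  cfg <- list(
    n_genes = n_genes, n_samples_base = n_samples_base,
    n_samples_tissue = n_samples_tissue, n_latent_factors = n_latent_factors,
    n_modules = n_modules, module_size = module_size,
    tissue_specific_modules = as.integer(tissue_specific_modules),
    loading_strength = loading_strength, nb_dispersion = nb_dispersion,
    mean_log_expression = mean_log_expression,
    library_size_sigma = library_size_sigma, batch_effect = batch_effect,
    annotation_noise = annotation_noise, n_terms = n_terms,
    positives_per_term = positives_per_term, seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop_nephronet(sprintf("invalid simulation config: `%s` %s", field, why),
                   "nephronet_config_error")
  }
  for (f in c("n_genes", "n_samples_base", "n_samples_tissue",
              "n_latent_factors", "n_modules", "module_size",
              "n_terms", "positives_per_term")) {
    if (!is_count_scalar(cfg[[f]])) bad(f, "must be a positive integer")
  }
  if (!is_prob_scalar(cfg$annotation_noise)) bad("annotation_noise", "must lie in [0, 1]")
  if (!is.numeric(cfg$loading_strength) || length(cfg$loading_strength) != 1 ||
      !is.finite(cfg$loading_strength) || cfg$loading_strength < 0) {
    bad("loading_strength", "must be a nonnegative real")
  }
  if (!is.numeric(cfg$nb_dispersion) || cfg$nb_dispersion <= 0) {
    bad("nb_dispersion", "must be > 0")
  }
  if (!is.numeric(cfg$library_size_sigma) || cfg$library_size_sigma < 0) {
    bad("library_size_sigma", "must be >= 0")
  }
  if (!is.numeric(cfg$mean_log_expression) || !is.finite(cfg$mean_log_expression)) {
    bad("mean_log_expression", "must be a finite real")
  }
  if (cfg$n_modules * cfg$module_size > cfg$n_genes) {
    bad("module_size", "violates n_modules * module_size <= n_genes")
  }
  if (cfg$positives_per_term > cfg$module_size) {
    bad("positives_per_term", "must not exceed module_size")
  }
  if (length(cfg$tissue_specific_modules) &&
      (any(cfg$tissue_specific_modules < 1) ||
       any(cfg$tissue_specific_modules > cfg$n_modules))) {
    bad("tissue_specific_modules", "indices must lie in 1..n_modules")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || !is.finite(cfg$seed)) {
    bad("seed", "must be a single finite number")
  }
  invisible(cfg)
}

#' Simulate a two-compendium expression study with planted phenotype signal
#'
#' Counts for gene g, sample s are negative binomial with mean
#' `exp(base_g + sum_f loading[g, f] * factor[s, f] + batch shift) * size_s`.
#' Each module's genes share one latent factor with loading
#' `loading_strength`; tissue-specific modules have that loading zeroed in the
#' base compendium. Each phenotype term draws its positive genes from one
#' module, with a fraction `annotation_noise` replaced by background genes.
#'
#' @param config A [sim_config()].
#' @return A `simulated_study` list: `base_counts` and `tissue_counts`
#'   (expression tables at stage `raw_counts`), `covariates_base` /
#'   `covariates_tissue` (tibbles: `sample_id`, `batch`), `annotations`
#'   (an [annotation_set()]; terms for tissue-specific modules carry the
#'   group tag `"tissue_specific"`), `truth` (named list: term id -> full
#'   planted module gene set), and `config`.
#' @examples
#' study <- simulate_study(sim_config(n_genes = 200, n_samples_base = 30,
#'                                    n_samples_tissue = 20, module_size = 20,
#'                                    positives_per_term = 10, seed = 7))
#' dim(expr_values(study$base_counts))
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, as.list(config))
  }
  validate_sim_config(config)
  with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  n_fac <- cfg$n_latent_factors + cfg$n_modules

  module_genes <- lapply(seq_len(cfg$n_modules), function(m) {
    genes[((m - 1) * cfg$module_size + 1):(m * cfg$module_size)]
  })
  names(module_genes) <- paste0("module", seq_len(cfg$n_modules))

  # loadings: dense weak background factors + one strong factor per module
  load_mat <- matrix(rnorm(cfg$n_genes * n_fac, sd = 0.15), cfg$n_genes, n_fac)
  for (m in seq_len(cfg$n_modules)) {
    idx <- ((m - 1) * cfg$module_size + 1):(m * cfg$module_size)
    load_mat[, cfg$n_latent_factors + m] <- 0
    load_mat[idx, cfg$n_latent_factors + m] <- cfg$loading_strength
  }
  base_load <- load_mat
  if (length(cfg$tissue_specific_modules)) {
    base_load[, cfg$n_latent_factors + cfg$tissue_specific_modules] <- 0
  }

  gene_base <- cfg$mean_log_expression + rnorm(cfg$n_genes, sd = 1)

  draw_compendium <- function(loadings, n_samples, prefix) {
    fac <- matrix(rnorm(n_samples * n_fac), n_samples, n_fac)
    batch <- rep(c(0L, 1L), length.out = n_samples)
    size <- rlnorm(n_samples, 0, cfg$library_size_sigma)
    log_mu <- gene_base + loadings %*% t(fac) +
      matrix(cfg$batch_effect * batch, cfg$n_genes, n_samples, byrow = TRUE)
    mu <- exp(log_mu) * matrix(size, cfg$n_genes, n_samples, byrow = TRUE)
    counts <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = 1 / cfg$nb_dispersion),
      cfg$n_genes, n_samples,
      dimnames = list(genes, sprintf("%s_s%03d", prefix, seq_len(n_samples)))
    )
    list(counts = expression_table(counts, "raw_counts"),
         covariates = tibble(sample_id = colnames(counts), batch = batch))
  }

  base <- draw_compendium(base_load, cfg$n_samples_base, "base")
  tissue <- draw_compendium(load_mat, cfg$n_samples_tissue, "tissue")

  # annotations: one term per module (round-robin), with label noise
  term_ids <- sprintf("T%04d", seq_len(cfg$n_terms))
  truth <- list()
  assoc <- vector("list", cfg$n_terms)
  tags <- vector("list", cfg$n_terms)
  for (t in seq_len(cfg$n_terms)) {
    m <- ((t - 1) %% cfg$n_modules) + 1
    truth[[term_ids[t]]] <- module_genes[[m]]
    pos <- sample(module_genes[[m]], cfg$positives_per_term)
    n_noise <- round(cfg$annotation_noise * cfg$positives_per_term)
    if (n_noise > 0) {
      background <- setdiff(genes, module_genes[[m]])
      pos[seq_len(n_noise)] <- sample(background, n_noise)
    }
    assoc[[t]] <- tibble(gene_id = sort(unique(pos)), term_id = term_ids[t],
                         term_name = sprintf("%s phenotype", names(module_genes)[m]),
                         provenance = "curated")
    tags[[t]] <- if (m %in% cfg$tissue_specific_modules) "tissue_specific" else character()
  }
  associations <- bind_rows(assoc)
  anns <- annotation_set(associations)
  for (t in seq_len(cfg$n_terms)) {
    if (length(tags[[t]])) anns <- tag_term_group(anns, tags[[t]], term_ids[t])
  }

  structure(
    list(base_counts = base$counts, tissue_counts = tissue$counts,
         covariates_base = base$covariates, covariates_tissue = tissue$covariates,
         annotations = anns, truth = truth, modules = module_genes,
         config = cfg),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<simulated_study> %d genes; base %d samples, tissue %d samples; %d modules (%s tissue-specific); %d terms\n",
    cfg$n_genes, cfg$n_samples_base, cfg$n_samples_tissue, cfg$n_modules,
    length(cfg$tissue_specific_modules), cfg$n_terms))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits counts TSVs (genes as rows, header = sample IDs), covariate TSVs,
#' the annotation TSV in the dialect [parse_annotations()] reads, and a truth
#' JSON mapping each term to its planted module gene set.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a character vector of written file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    base_counts = file.path(dir, "base_counts.tsv"),
    tissue_counts = file.path(dir, "tissue_counts.tsv"),
    covariates_base = file.path(dir, "covariates_base.tsv"),
    covariates_tissue = file.path(dir, "covariates_tissue.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_counts(study$base_counts, paths["base_counts"])
  write_counts(study$tissue_counts, paths["tissue_counts"])
  readr::write_tsv(study$covariates_base, paths["covariates_base"])
  readr::write_tsv(study$covariates_tissue, paths["covariates_tissue"])
  write_annotations(study$annotations, paths["annotations"])
  jsonlite::write_json(study$truth, paths["truth"])
  invisible(paths)
}
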