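# End-to-end pipeline: preprocess both compendia, decompose each, merge,
# predict, evaluate; every artifact is written under the output directory and
# listed in a manifest with content hashes so a rerun with the same config and
# seed is verifiable.

#' Assemble a pipeline run configuration
#'
#' Either `simulate` (a [sim_config()] or list of its arguments) or the four
#' input paths (`base_counts`, `tissue_counts`, covariates, `annotations`)
#' must be provided. All stage parameters have defaults; any can be overridden.
#' All randomness flows from `seed` via stage-name-derived seeds.
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @param simulate Optional [sim_config()] (or argument list) to generate the
#'   inputs instead of reading them.
#' @param inputs Optional named list of file paths: `base_counts`,
#'   `tissue_counts`, `covariates_base`, `covariates_tissue`, `annotations`.
#' @param preprocess,decompose,annotate,predict,evaluate Named lists of stage
#'   parameter overrides; see the corresponding functions for meanings.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, simulate = NULL, inputs = NULL,
                       preprocess = list(), decompose = list(),
                       annotate = list(), predict = list(), evaluate = list()) {
  defaults <- list(
    preprocess = list(min_gene_count = 5, min_gene_samples = 10,
                      min_sample_total = 0, pseudocount = 1),
    decompose = list(k_base = 10, k_tissue = 10, gene_policy = "intersection"),
    annotate = list(exclude_flags = c("multigenic_syndrome", "susceptibility"),
                    min_genes_per_term = 10),
    predict = list(ridge_penalty = 1, n_permutations = 200),
    evaluate = list(alpha = 0.05, z_threshold = 5)
  )
  cfg <- list(
    out_dir = out_dir, seed = seed, simulate = simulate, inputs = inputs,
    preprocess = modifyList(defaults$preprocess, preprocess),
    decompose = modifyList(defaults$decompose, decompose),
    annotate = modifyList(defaults$annotate, annotate),
    predict = modifyList(defaults$predict, predict),
    evaluate = modifyList(defaults$evaluate, evaluate)
  )
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    stop_nephronet("run_config needs either `simulate` or `inputs`",
                   "nephronet_config_error")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' File keys mirror the [run_config()] arguments; `overrides` (e.g. parsed
#' CLI flags) win over file values.
#'
#' @param path `.yaml`/`.yml` or `.json` config file.
#' @param overrides Named list merged over the file contents.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) {
    stop_nephronet(sprintf("config file not found: %s", path), "nephronet_io_error")
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  raw <- modifyList(raw, overrides)
  do.call(run_config, raw)
}

#' Run the full network-building pipeline
#'
#' Stages, in order: simulate (or read inputs), preprocess (QC,
#' median-of-ratios, log2, covariate residualization) per compendium,
#' decompose per compendium, merge, predict (leave-one-out log-odds +
#' permutation z per term), evaluate. Every artifact is written under
#' `config$out_dir` and hashed into the returned manifest; a failing stage
#' aborts with the stage name and renames that stage's partial outputs with a
#' `.partial` suffix.
#'
#' @param config A [run_config()] or [read_run_config()] result.
#' @return A manifest tibble: `stage`, `file`, `md5`. The evaluation table is
#'   also attached as attribute `"evaluation"`, and the prediction matrix as
#'   `"predictions"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  add <- function(stage, ...) {
    files <- c(...)
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, file = unname(files),
      md5 = unname(tools::md5sum(unname(files))))
  }
  stage_files <- character()
  run_stage <- function(name, params, code) {
    inform(sprintf("[nephronet] stage %s: %s", name,
                   paste(names(params), unlist(lapply(params, paste, collapse = ",")),
                         sep = "=", collapse = " ")))
    stage_files <<- character()
    tryCatch(code, error = function(e) {
      for (f in stage_files[file.exists(stage_files)]) {
        file.rename(f, paste0(f, ".partial"))
      }
      stop_nephronet(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                     "nephronet_stage_error")
    })
  }
  out <- function(name) {
    f <- file.path(config$out_dir, name)
    stage_files <<- c(stage_files, f, paste0(f, ".json"))
    f
  }

  # ---- inputs ----
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (!inherits(sim, "sim_config")) {
      sim$seed <- sim$seed %||% derive_seed(config$seed, "simulate")
      sim <- do.call(sim_config, sim)
    }
    study <- run_stage("simulate", list(seed = sim$seed), simulate_study(sim))
    paths <- write_study(study, config$out_dir)
    add("simulate", paths)
    base_counts <- study$base_counts; tissue_counts <- study$tissue_counts
    cov_base <- study$covariates_base; cov_tissue <- study$covariates_tissue
    anns <- study$annotations
  } else {
    inp <- config$inputs
    base_counts <- run_stage("read", inp, read_counts(inp$base_counts))
    tissue_counts <- read_counts(inp$tissue_counts)
    cov_base <- if (!is.null(inp$covariates_base)) read_covariates(inp$covariates_base)
    cov_tissue <- if (!is.null(inp$covariates_tissue)) read_covariates(inp$covariates_tissue)
    anns <- parse_annotations(inp$annotations)
  }

  # ---- annotate (filtering) ----
  pa <- config$annotate
  anns <- run_stage("annotate", pa,
                    filter_annotations(anns, pa$exclude_flags, pa$min_genes_per_term))

  # ---- preprocess ----
  pp <- config$preprocess
  processed <- run_stage("preprocess", pp, {
    list(
      base = preprocess_counts(base_counts, cov_base, pp$min_gene_count,
                               pp$min_gene_samples, pp$min_sample_total,
                               pp$pseudocount),
      tissue = preprocess_counts(tissue_counts, cov_tissue, pp$min_gene_count,
                                 pp$min_gene_samples, pp$min_sample_total,
                                 pp$pseudocount))
  })

  # ---- decompose + merge ----
  dc <- config$decompose
  merged <- run_stage("decompose", dc, {
    eig_base <- compute_components(processed$base, dc$k_base, "base")
    eig_tissue <- compute_components(processed$tissue, dc$k_tissue, "tissue")
    write_eigenvectors(eig_base, out("eigenvectors_base.tsv"))
    write_eigenvectors(eig_tissue, out("eigenvectors_tissue.tsv"))
    merge_components(eig_base, eig_tissue, dc$gene_policy)
  })
  add("decompose", file.path(config$out_dir,
                             c("eigenvectors_base.tsv", "eigenvectors_base.tsv.json",
                               "eigenvectors_tissue.tsv", "eigenvectors_tissue.tsv.json")))

  # ---- predict ----
  pr <- config$predict
  pred <- run_stage("predict", pr,
                    predict_terms(merged, anns, pr$ridge_penalty,
                                  pr$n_permutations,
                                  seed = derive_seed(config$seed, "predict")))
  write_predictions(pred, out("predictions.tsv"))
  add("predict", file.path(config$out_dir, c("predictions.tsv", "predictions.tsv.json")))

  # ---- evaluate ----
  ev <- config$evaluate
  evaluation <- run_stage("evaluate", ev,
                          evaluate_network(pred, anns, ev$alpha, ev$z_threshold))
  eval_path <- file.path(config$out_dir, "evaluation.tsv")
  readr::write_tsv(
    mutate(evaluation,
           group_tags = vapply(.data$group_tags, paste, character(1), collapse = ";")),
    eval_path)
  add("evaluate", eval_path)

  manifest <- bind_rows(manifest)
  attr(manifest, "evaluation") <- evaluation
  attr(manifest, "predictions") <- pred
  manifest
}
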