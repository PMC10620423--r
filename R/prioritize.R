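# Patient-level candidate gene prioritization: Stouffer-combined z over the
# patient's phenotype terms (candidates at combined z >= 5), intersected with
# a rare-variant filter (population AF < 0.005, pathogenicity score >= 0.0027
# by default), plus cohort allele-count enrichment by Fisher's exact test.

#' Construct a patient case
#'
#' @param case_id Case identifier.
#' @param hpo_terms Nonempty character vector of unique phenotype term IDs.
#' @param variants Tibble/data frame with columns `gene_id`, `popmax_af`
#'   (population maximum allele frequency, in \[0, 1\]) and
#'   `pathogenicity_score` (e.g. a CAPICE score, in \[0, 1\]); one row per
#'   variant, genes may repeat.
#' @return A `patient_case`.
#' @export
patient_case <- function(case_id, hpo_terms, variants) {
  if (length(hpo_terms) == 0 || anyDuplicated(hpo_terms) ||
      any(!nzchar(hpo_terms))) {
    stop_nephronet("hpo_terms must be nonempty and unique", "nephronet_format_error")
  }
  variants <- as_tibble(variants)
  required <- c("gene_id", "popmax_af", "pathogenicity_score")
  if (!all(required %in% names(variants))) {
    stop_nephronet(sprintf("variants need columns: %s", paste(required, collapse = ", ")),
                   "nephronet_format_error")
  }
  bad <- !is.finite(variants$popmax_af) | variants$popmax_af < 0 |
    variants$popmax_af > 1 | !is.finite(variants$pathogenicity_score) |
    variants$pathogenicity_score < 0 | variants$pathogenicity_score > 1
  if (any(bad)) {
    stop_nephronet("variant AFs and pathogenicity scores must lie in [0, 1]",
                   "nephronet_format_error")
  }
  structure(list(case_id = case_id, hpo_terms = as.character(hpo_terms),
                 variants = variants[, required]),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %s: %d phenotype term(s), %d variant(s) in %d gene(s)\n",
              x$case_id, length(x$hpo_terms), nrow(x$variants),
              dplyr::n_distinct(x$variants$gene_id)))
  invisible(x)
}

#' Read a patient case from JSON
#'
#' Expects `{"case_id": ..., "hpo_terms": [...], "variants":
#' [{"gene": ..., "popmax_af": ..., "capice": ...}, ...]}`; the variant fields
#' also accept `gene_id` / `af` / `pathogenicity_score` / `score` spellings.
#'
#' @param path JSON file path.
#' @return A [patient_case()].
#' @export
read_patient_case <- function(path) {
  if (!file.exists(path)) {
    stop_nephronet(sprintf("case file not found: %s", path), "nephronet_io_error")
  }
  raw <- jsonlite::fromJSON(path)
  v <- as_tibble(raw$variants)
  pick <- function(candidates) {
    hit <- intersect(candidates, names(v))
    if (length(hit) == 0) {
      stop_nephronet(sprintf("case variants lack a column among: %s",
                             paste(candidates, collapse = ", ")),
                     "nephronet_format_error")
    }
    v[[hit[1]]]
  }
  variants <- tibble(gene_id = as.character(pick(c("gene_id", "gene"))),
                     popmax_af = as.numeric(pick(c("popmax_af", "af"))),
                     pathogenicity_score = as.numeric(
                       pick(c("pathogenicity_score", "capice", "score"))))
  patient_case(raw$case_id, unlist(raw$hpo_terms), variants)
}

#' Stouffer combination of per-term z-scores
#'
#' `sum(z) / sqrt(k)` over the k finite entries; non-finite entries are
#' skipped with k reduced. All-missing input yields `NA` with a warning.
#'
#' @param z_values Numeric z-scores for one gene across terms.
#' @return A single combined z.
#' @export
combine_z <- function(z_values) {
  z <- z_values[is.finite(z_values)]
  if (length(z) == 0) {
    warn("combine_z(): no finite z-score; returning NA")
    return(NA_real_)
  }
  sum(z) / sqrt(length(z))
}

#' Keep genes at or above the combined-z candidate threshold
#'
#' @param combined Tibble with columns `gene_id`, `combined_z`.
#' @param cutoff Inclusive threshold (candidates satisfy `combined_z >= cutoff`).
#' @return The qualifying rows, ordered by `combined_z` descending (ties by
#'   gene ID).
#' @export
threshold_candidates <- function(combined, cutoff = 5) {
  stopifnot(is.data.frame(combined),
            all(c("gene_id", "combined_z") %in% names(combined)))
  combined |>
    filter(is.finite(.data$combined_z), .data$combined_z >= cutoff) |>
    arrange(desc(.data$combined_z), .data$gene_id)
}

#' Genes with at least one filter-passing variant
#'
#' A variant passes when its population AF is strictly below `af_max` and its
#' pathogenicity score is at least `score_min` (inclusive); a gene passes when
#' any of its variants does.
#'
#' @param case A [patient_case()].
#' @param af_max Population-AF upper bound (strict `<`).
#' @param score_min Pathogenicity-score lower bound (inclusive `>=`).
#' @return Tibble `gene_id`, `n_passing_variants`, one row per passing gene.
#' @export
filter_variants <- function(case, af_max = 0.005, score_min = 0.0027) {
  stopifnot(inherits(case, "patient_case"))
  if (!is_prob_scalar(af_max) || !is_prob_scalar(score_min)) {
    stop_nephronet("af_max and score_min must lie in [0, 1]", "nephronet_config_error")
  }
  case$variants |>
    filter(.data$popmax_af < af_max, .data$pathogenicity_score >= score_min) |>
    dplyr::count(.data$gene_id, name = "n_passing_variants") |>
    arrange(.data$gene_id)
}

#' Prioritize candidate genes for one patient
#'
#' Combines each gene's per-term prediction z-scores over the case's phenotype
#' terms (Stouffer), keeps genes with combined z at or above `cutoff`, and
#' intersects with the genes passing the variant filter. Case terms absent
#' from the prediction matrix are dropped with a warning; if none remain the
#' call errors.
#'
#' @param case A [patient_case()].
#' @param predictions A [predict_terms()] result with z-scores.
#' @param cutoff Inclusive combined-z candidate threshold.
#' @inheritParams filter_variants
#' @return A `candidate_list`: `$ranking` is a tibble of the genes passing the
#'   z threshold (columns `gene_id`, `combined_z`, `n_terms_used`, per-term
#'   `z_<term>` columns, `passed_variant_filter`, `candidate`), sorted by
#'   combined z descending with ties broken by gene ID. `candidates()`
#'   extracts the intersection.
#' @export
prioritize_case <- function(case, predictions, cutoff = 5, af_max = 0.005,
                            score_min = 0.0027) {
  stopifnot(inherits(case, "patient_case"),
            inherits(predictions, "prediction_matrix"))
  have <- colnames(predictions$z)
  terms <- intersect(case$hpo_terms, have)
  missing <- setdiff(case$hpo_terms, have)
  if (length(terms) == 0) {
    stop_nephronet(sprintf("none of case %s's terms are in the prediction matrix",
                           case$case_id),
                   "nephronet_prioritization_error")
  }
  if (length(missing)) {
    warn(sprintf("prioritize_case(): dropping term(s) absent from predictions: %s",
                 paste(missing, collapse = ", ")))
  }
  zmat <- predictions$z[, terms, drop = FALSE]
  if (all(!is.finite(zmat))) {
    stop_nephronet("prediction matrix has no z-scores (run predict_terms with permutations)",
                   "nephronet_prioritization_error")
  }
  combined <- tibble(
    gene_id = rownames(zmat),
    combined_z = unname(apply(zmat, 1, function(z) {
      zf <- z[is.finite(z)]
      if (length(zf) == 0) NA_real_ else sum(zf) / sqrt(length(zf))
    })),
    n_terms_used = unname(apply(zmat, 1, function(z) sum(is.finite(z))))
  )
  z_cols <- as_tibble(zmat, .name_repair = ~ paste0("z_", terms))
  combined <- bind_cols(combined, z_cols)

  passing <- filter_variants(case, af_max, score_min)
  ranking <- threshold_candidates(combined, cutoff) |>
    mutate(passed_variant_filter = .data$gene_id %in% passing$gene_id,
           candidate = .data$passed_variant_filter)
  structure(list(case_id = case$case_id, ranking = ranking, terms_used = terms,
                 dropped_terms = missing, cutoff = cutoff,
                 af_max = af_max, score_min = score_min,
                 n_variant_pass = nrow(passing)),
            class = "candidate_list")
}

#' @export
print.candidate_list <- function(x, ...) {
  cat(sprintf("<candidate_list> case %s: %d gene(s) at combined z >= %g, %d also pass the variant filter\n",
              x$case_id, nrow(x$ranking), x$cutoff, sum(x$ranking$candidate)))
  invisible(x)
}

#' Extract the final candidate genes (z threshold AND variant filter)
#'
#' @param x A `candidate_list`.
#' @return Tibble of candidate rows, ranked by combined z.
#' @export
candidates <- function(x) {
  stopifnot(inherits(x, "candidate_list"))
  filter(x$ranking, .data$candidate)
}

#' Cohort allele-count enrichment (Fisher's exact test)
#'
#' Builds the 2x2 table
#' `[[carriers_cohort, alleles_cohort - carriers_cohort],
#'   [carriers_ref, alleles_ref - carriers_ref]]` and reports the two-sided
#' exact p (point-probability rule: sum over tables with fixed margins whose
#' probability does not exceed the observed table's) together with the
#' cross-product odds ratio (`Inf` sentinel when a zero cell makes the
#' denominator vanish).
#'
#' @param carriers_cohort,alleles_cohort Variant allele count and total allele
#'   count in the phenotype-defined cohort.
#' @param carriers_ref,alleles_ref The same in the reference population.
#' @return One-row tibble: `odds_ratio`, `p_value`.
#' @export
fisher_enrichment <- function(carriers_cohort, alleles_cohort,
                              carriers_ref, alleles_ref) {
  counts <- c(carriers_cohort, alleles_cohort, carriers_ref, alleles_ref)
  if (any(!is.finite(counts) | counts < 0 | counts != floor(counts)) ||
      carriers_cohort > alleles_cohort || carriers_ref > alleles_ref ||
      alleles_cohort == 0 || alleles_ref == 0) {
    stop_nephronet("counts must be nonnegative integers with carriers <= alleles > 0",
                   "nephronet_validation_error")
  }
  tab <- matrix(c(carriers_cohort, alleles_cohort - carriers_cohort,
                  carriers_ref, alleles_ref - carriers_ref),
                nrow = 2, byrow = TRUE)
  p <- fisher.test(tab)$p.value
  num <- tab[1, 1] * tab[2, 2]
  den <- tab[1, 2] * tab[2, 1]
  or <- if (den == 0) {
    if (num == 0) NA_real_ else Inf
  } else num / den
  tibble(odds_ratio = or, p_value = min(1, p))
}
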