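test_that("Stouffer combination follows its closed forms", {
  expect_equal(combine_z(5.43), 5.43)                    # single-term identity
  expect_equal(combine_z(c(3, 3)), 3 * sqrt(2))
  expect_equal(combine_z(c(2, -2)), 0)
  # k copies of z combine to z * sqrt(k)
  for (k in c(2, 5, 9)) expect_equal(combine_z(rep(1.7, k)), 1.7 * sqrt(k))
  # non-finite entries are skipped with k reduced
  expect_equal(combine_z(c(3, NA, 3)), 3 * sqrt(2))
  expect_warning(out <- combine_z(c(NA_real_, NaN)), "no finite")
  expect_true(is.na(out))
})

test_that("the combined-z threshold is inclusive at the cutoff", {
  tbl <- tibble::tibble(gene_id = c("B", "A", "C"),
                        combined_z = c(5.0, 4.999, 7.2))
  out <- threshold_candidates(tbl, cutoff = 5)
  expect_identical(out$gene_id, c("C", "B"))   # 5.0 kept, 4.999 dropped
  expect_identical(nrow(threshold_candidates(tbl[0, ], 5)), 0L)
})

test_that("variant filtering applies strict AF and inclusive score bounds", {
  case <- patient_case("P1", "HP:1",
    tibble::tibble(
      gene_id = c("AF_AT_BOUND", "SCORE_AT_BOUND", "BOTH_PASS", "TWO_VAR", "TWO_VAR"),
      popmax_af = c(0.005, 0.001, 0.001, 0.9, 0.0001),
      pathogenicity_score = c(0.5, 0.0027, 0.8, 0.9, 0.5)))
  out <- filter_variants(case)
  expect_setequal(out$gene_id, c("SCORE_AT_BOUND", "BOTH_PASS", "TWO_VAR"))
  expect_identical(out$n_passing_variants[out$gene_id == "TWO_VAR"], 1L)
  expect_false("AF_AT_BOUND" %in% out$gene_id)  # AF < 0.005 is strict
})

test_that("patient cases validate and round-trip through JSON", {
  expect_error(patient_case("P", character(), tibble::tibble()),
               class = "nephronet_format_error")
  expect_error(patient_case("P", c("T1", "T1"),
                            tibble::tibble(gene_id = "G", popmax_af = 0.1,
                                           pathogenicity_score = 0.1)),
               class = "nephronet_format_error")
  expect_error(patient_case("P", "T1",
                            tibble::tibble(gene_id = "G", popmax_af = 2,
                                           pathogenicity_score = 0.1)),
               class = "nephronet_format_error")

  path <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(case_id = "CASE6",
         hpo_terms = c("HP:0000107", "HP:0001407"),
         variants = data.frame(gene = c("ALG6", "PKD1"),
                               popmax_af = c(8.02e-6, 0.2),
                               capice = c(0.9, 0.01))),
    path, auto_unbox = TRUE)
  case <- read_patient_case(path)
  expect_identical(case$case_id, "CASE6")
  expect_identical(case$hpo_terms, c("HP:0000107", "HP:0001407"))
  expect_identical(case$variants$gene_id, c("ALG6", "PKD1"))
  expect_equal(case$variants$pathogenicity_score, c(0.9, 0.01))
})

make_case_predictions <- function(z_by_gene, terms = c("T1", "T2")) {
  z <- matrix(rep(z_by_gene, length(terms)), ncol = length(terms),
              dimnames = list(names(z_by_gene), terms))
  make_predictions(z)
}

test_that("prioritization ranks by combined z and intersects the variant filter", {
  genes <- paste0("G", 1:10)
  set.seed(71)
  z1 <- setNames(c(8, 7, 7, 6, 3, 2, 1, 0, -1, -2), genes)
  z2 <- setNames(c(6, 7, 7, 9, 2, 1, 0, 0, -1, -2), genes)
  pred <- make_predictions(cbind(T1 = z1, T2 = z2))
  case <- patient_case("P1", c("T1", "T2"),
    tibble::tibble(gene_id = c("G2", "G4", "G9"),
                   popmax_af = c(1e-4, 1e-4, 1e-4),
                   pathogenicity_score = c(0.9, 0.9, 0.9)))
  cl <- prioritize_case(case, pred, cutoff = 5)
  # manual sort oracle
  combined <- (z1 + z2) / sqrt(2)
  expected <- sort(combined[combined >= 5], decreasing = TRUE)
  expect_identical(cl$ranking$gene_id, names(expected))
  expect_equal(cl$ranking$combined_z, unname(expected))
  # ties broken by gene ID: G2 and G3 both combine to 14/sqrt(2)
  expect_lt(which(cl$ranking$gene_id == "G2"), which(cl$ranking$gene_id == "G3"))
  # intersection semantics: G1 passes z but has no qualifying variant
  expect_false(cl$ranking$candidate[cl$ranking$gene_id == "G1"])
  expect_setequal(candidates(cl)$gene_id, c("G2", "G4"))
  # invariant to gene order in the inputs
  perm <- sample(10)
  pred2 <- make_predictions(cbind(T1 = z1[perm], T2 = z2[perm]))
  cl2 <- prioritize_case(case, pred2, cutoff = 5)
  expect_identical(cl2$ranking, cl$ranking)
})

test_that("missing case terms are dropped with a warning, all-missing errors", {
  z <- setNames(c(6, 1), c("G1", "G2"))
  pred <- make_case_predictions(z, "T1")
  case <- patient_case("P1", c("T1", "T9"),
    tibble::tibble(gene_id = "G1", popmax_af = 0.0001,
                   pathogenicity_score = 0.9))
  expect_warning(cl <- prioritize_case(case, pred), "T9")
  expect_identical(cl$dropped_terms, "T9")
  expect_identical(candidates(cl)$gene_id, "G1")

  case2 <- patient_case("P2", "T9",
    tibble::tibble(gene_id = "G1", popmax_af = 0.0001,
                   pathogenicity_score = 0.9))
  expect_error(prioritize_case(case2, pred),
               class = "nephronet_prioritization_error")
})

test_that("Fisher enrichment matches brute-force hypergeometric enumeration", {
  # brute-force oracle: all tables with the observed margins
  fisher_bruteforce <- function(a, m, c, n) {
    tab <- c(a, m - a, c, n - c)
    k <- a + c              # total carriers
    prob <- function(x) dhyper(x, m, n, k)
    p_obs <- prob(a)
    sum(vapply(max(0, k - n):min(k, m),
               function(x) if (prob(x) <= p_obs * (1 + 1e-7)) prob(x) else 0,
               numeric(1)))
  }
  res <- fisher_enrichment(2, 5, 4, 5)
  expect_equal(res$p_value, fisher_bruteforce(2, 5, 4, 5), tolerance = 1e-10)
  res2 <- fisher_enrichment(3, 12, 1, 9)
  expect_equal(res2$p_value, fisher_bruteforce(3, 12, 1, 9), tolerance = 1e-10)

  # identical proportions are not enriched
  expect_equal(fisher_enrichment(1, 2, 1, 2)$p_value, 1)

  # swapping the rows keeps p and inverts the cross-product odds ratio
  f1 <- fisher_enrichment(3, 210, 121, 128932)
  f2 <- fisher_enrichment(121, 128932, 3, 210)
  expect_equal(f1$p_value, f2$p_value)
  expect_equal(f1$odds_ratio, 1 / f2$odds_ratio)
  # cross-product ratio, not the conditional MLE
  expect_equal(f1$odds_ratio, (3 * (128932 - 121)) / ((210 - 3) * 121))

  # zero-cell sentinel and validation
  expect_identical(fisher_enrichment(2, 2, 0, 10)$odds_ratio, Inf)
  expect_error(fisher_enrichment(5, 2, 1, 10), class = "nephronet_validation_error")
  expect_error(fisher_enrichment(0, 0, 1, 10), class = "nephronet_validation_error")
})

test_that("p-values stay in (0, 1] under random valid tables", {
  set.seed(72)
  for (i in 1:50) {
    a1 <- sample(0:20, 1); n1 <- a1 + sample(0:50, 1)
    a2 <- sample(0:20, 1); n2 <- a2 + sample(0:50, 1)
    if (n1 == 0 || n2 == 0) next
    p <- fisher_enrichment(a1, n1, a2, n2)$p_value
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("the planted causal gene tops the candidate list in seeded replicates", {
  # one network at the generator's default signal strength; the patient
  # scenario of interest is a causal gene that is co-expressed with the
  # term's known genes but not itself annotated (the discovery setting)
  study <- simulate_study(sim_config(seed = 73))
  pb <- preprocess_counts(study$base_counts, study$covariates_base,
                          min_sample_total = 0)
  pt <- preprocess_counts(study$tissue_counts, study$covariates_tissue,
                          min_sample_total = 0)
  mc <- merge_components(compute_components(pb, 10, "base"),
                         compute_components(pt, 10, "tissue"))
  pred <- predict_terms(mc, study$annotations, n_permutations = 200, seed = 73)
  amat <- annotation_matrix(study$annotations, rownames(pred$z))
  genes <- rownames(pred$z)

  hits <- 0
  set.seed(74)
  for (r in 1:100) {
    t <- sample(colnames(pred$z), 1)
    detectable <- setdiff(genes[genes %in% study$truth[[t]] & pred$z[, t] >= 5],
                          genes[amat[, t] == 1])
    if (length(detectable) == 0) next
    causal <- sample(detectable, 1)
    # rare variants land in genes unrelated to the phenotype's module
    unrelated <- setdiff(genes, c(study$truth[[t]], genes[amat[, t] == 1]))
    decoys <- sample(unrelated, 30)
    case <- patient_case(paste0("R", r), t,
      tibble::tibble(gene_id = c(causal, decoys),
                     popmax_af = c(1e-4, rep(1e-4, 30)),
                     pathogenicity_score = c(0.8, rep(0.6, 30))))
    cand <- candidates(prioritize_case(case, pred, cutoff = 5))
    if (nrow(cand) > 0 && cand$gene_id[1] == causal) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
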