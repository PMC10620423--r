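# nephronet

Tissue-aware gene–phenotype prediction networks from bulk RNA-seq compendia,
with patient-level candidate gene prioritization.

## What it is for

Genetic testing in suspected hereditary disease often ends without a
diagnosis because the causal variant sits in a gene not yet linked to the
phenotype. Genes that cause the same rare disorder are usually strongly
co-expressed, so large RNA-seq compendia carry usable evidence about which
unannotated genes "behave like" a phenotype's known genes. nephronet builds
that evidence into calibrated per-gene, per-phenotype scores, and is aimed at
statistical geneticists and nephrogenetics-style research groups who want to
rank candidate genes for undiagnosed patients — and at method developers, who
get a synthetic-data generator that makes the whole pipeline testable offline.

## The method

1. **Preprocess** each compendium: QC filters, median-of-ratios size factors
   (per sample, median over genes of `count / geometric mean`), `log2(x/s + 1)`,
   and OLS residualization on sample covariates.
2. **Decompose**: SVD of the per-gene standardized matrix; each gene gets a
   loading on the top *K* components (eigenvectors of the gene correlation
   matrix). Loadings from a large multi-tissue compendium and a smaller
   tissue-specific compendium are merged column-wise.
3. **Score**: per phenotype term, a ridge-penalized logistic regression of the
   gene annotations on the merged loadings gives

       log-odds_g = β₀ + β₁·u_g1 + … + β_K·u_gK

   Annotated genes are scored leave-one-out (exact refit without the gene);
   scores are standardized against a permutation null (labels reassigned at
   random, model refit, log-odds pooled over genes and permutations) into
   per-term z-scores.
4. **Evaluate**: per-term AUC (Mann–Whitney with midrank ties), two-sided
   Mann–Whitney significance with Bonferroni correction, and paired network
   comparison with the DeLong test for correlated AUCs.
5. **Prioritize**: for a patient, per-term z-scores over their phenotype terms
   are Stouffer-combined (`Σz/√k`); genes with combined z ≥ 5 are intersected
   with genes carrying a rare, plausibly pathogenic variant
   (population AF < 0.005, pathogenicity score ≥ 0.0027). Cohort-level support
   is tested with Fisher's exact test on carrier allele counts.

## Worked example

```r
library(nephronet)

study <- simulate_study(sim_config(seed = 1))      # two compendia + annotations
pb <- preprocess_counts(study$base_counts,  study$covariates_base,  min_sample_total = 0)
pt <- preprocess_counts(study$tissue_counts, study$covariates_tissue, min_sample_total = 0)
merged <- merge_components(compute_components(pb, 10, "base"),
                           compute_components(pt, 10, "tissue"))
pred <- predict_terms(merged, study$annotations, n_permutations = 200, seed = 1)
evaluate_network(pred)
```

```
# A tibble: 5 × 10
  term_id   auc    mwu_p significant n_pos n_neg precision sensitivity    f1 group_tags
  <chr>   <dbl>    <dbl> <lgl>       <int> <int>     <dbl>       <dbl> <dbl> <list>
1 T0001   0.922 7.97e-11 TRUE           20  1979     0.375        0.15 0.214 <chr [0]>
2 T0002   0.953 2.95e-12 TRUE           20  1979     0.333        0.25 0.286 <chr [0]>
3 T0003   0.963 1.00e-12 TRUE           20  1979     0.385        0.25 0.303 <chr [0]>
4 T0004   0.915 1.64e-10 TRUE           20  1979     0.667        0.5  0.571 <chr [1]>
5 T0005   0.909 3.04e-10 TRUE           20  1979     0.615        0.4  0.485 <chr [1]>
```

Every planted phenotype is recovered (AUC 0.91–0.96, all Bonferroni-
significant). The precision / sensitivity / F1 columns describe the
conservative z ≥ 5 candidate threshold: around 0.3–0.7 of called genes are
annotated ones, and the rest are mostly unannotated genes from the same
planted module — exactly the "plausible new candidate" behavior the method is
built for. Terms T0004/T0005 carry the `tissue_specific` group tag: their
modules express only in the tissue compendium, and a base-only network drops
to chance on them (mean AUC 0.912 vs 0.473 in the acceptance run below).
Patient prioritization then intersects combined z-scores with a variant
filter:

```r
case <- patient_case("CASE1", "T0001",
  tibble::tibble(gene_id = c("G00016", "G01000"),
                 popmax_af = c(1e-4, 1e-4),
                 pathogenicity_score = c(0.8, 0.6)))
candidates(prioritize_case(case, pred))
#>   gene_id combined_z n_terms_used z_T0001 passed_variant_filter candidate
#> 1 G00016        5.38            1    5.38 TRUE                  TRUE
fisher_enrichment(3, 210, 121, 128932)    # -> odds ratio 15.4, p = 0.00114
```

A command-line wrapper over the same functions ships at
`inst/cli/nephronet.R` (subcommands `simulate`, `preprocess`, `decompose`,
`predict`, `evaluate`, `compare`, `prioritize`, `fisher`, `run`).

## Acceptance script

`scripts/acceptance.R` re-runs the whole method from scratch: it simulates a
two-compendium study at the generator's default scale, builds and evaluates
the merged network, compares it against a base-only network on
tissue-specific terms, prioritizes a synthetic patient case, runs the cohort
allele-count enrichment example, and writes the results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Progress and summary numbers are logged to stderr.
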