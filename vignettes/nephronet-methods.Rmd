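---
title: "Methods: tissue-aware gene–phenotype prediction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-aware gene-phenotype prediction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Rare-disease gene discovery is limited by incomplete gene–phenotype
annotation: a patient's causal variant may sit in a gene nobody has yet linked
to the phenotype. Genes causing the same rare disorder tend to share biological
function and, in large RNA-seq compendia, to be strongly co-expressed. That
makes co-expression a usable prior: a gene that behaves transcriptionally like
the known genes of a phenotype is a plausible new candidate for it.

A single tissue rarely has enough public RNA-seq samples to support a
co-expression network on its own, while a large multi-tissue compendium
dilutes tissue-specific programs. nephronet implements the middle road: build
gene-level expression features from **both** a large multi-tissue compendium
and a smaller tissue-specific one, concatenate them, and let a supervised
model weigh the two sources per phenotype.

# The model

## Features: eigenvector loadings

Each processed compendium (QC → median-of-ratios size factors → `log2(x/s + 1)`
→ least-squares residualization on sample covariates) is reduced by singular
value decomposition of the per-gene standardized matrix. The gene-side
singular vectors give every gene a loading on each of the top *K* components;
this is equivalent to an eigendecomposition of the gene correlation matrix, so
components capture shared transcriptional programs. Loadings from the two
compendia are merged column-wise over the shared gene set (so e.g. 165 + 170
components become one 335-column feature matrix). Genes absent from one
compendium can alternatively be kept with zero-filled loadings
(`gene_policy = "union_zero_fill"`).

Numerical choices:

* **Sign convention.** Each component's largest-magnitude loading is made
  positive, so results are reproducible across linear-algebra backends.
* **Column scale.** Loadings are used as unit-norm singular vectors, not
  scaled by singular values; the regression absorbs scale (see below), and the
  per-column standardization inside the fit makes the two choices equivalent
  in practice.
* **Component count.** `select_component_count()` supports a fixed count (to
  mirror a published analysis), a cumulative variance fraction, and parallel
  analysis against permuted-gene singular values. There is no universally
  right answer; the pipeline default is a fixed, explicitly configured count.

## Per-phenotype scoring

For each phenotype term with at least two annotated genes, the binary
annotation vector is regressed on the merged loadings by logistic regression,
giving a gene log-odds score

$$\mathrm{log\text{-}odds}_g = \beta_0 + \beta_1 u_{g1} + \cdots + \beta_K u_{gK}.$$

Three safeguards make this usable at genome scale:

* **Ridge penalty on standardized features.** With hundreds of components and
  tens of positives, maximum likelihood is fragile (and undefined under
  separation). We maximize the log-likelihood minus
  $\tfrac{\lambda}{2}\lVert\beta\rVert_2^2$ (intercept unpenalized), with the
  penalty applied on per-column standardized features. This matters: unit-norm
  loading columns have entries of order $1/\sqrt{n_\mathrm{genes}}$, so a fixed
  penalty on the raw scale would crush every coefficient once the gene count
  grows. Standardizing inside the fit makes $\lambda$'s meaning independent of
  the loading normalization; coefficients are reported back on the input
  scale. Default $\lambda = 1$ (weak next to a likelihood over thousands of
  genes — stabilization, not shrinkage); $\lambda = 0$ gives plain maximum
  likelihood and fails loudly under separation.
* **Leave-one-out scoring.** An annotated gene scored by a model trained on
  its own label would be overrated. Every positive gene is therefore scored by
  a model refit without it (exact refit, warm-started from the full fit);
  negatives and unlabeled genes take the full-model score, bit-identical to
  `gene_log_odds()`. The package tests assert both properties.
* **Permutation-calibrated z-scores.** Raw log-odds are not comparable across
  terms. For each term we reassign the positive-label count uniformly at
  random over genes, refit, and pool the fitted log-odds of *all* genes across
  permutations (default 200) into a per-term null; the observed leave-one-out
  scores are standardized against that pool's mean and sd.

On the calibration of the pooled null: with $K$ merged components the spread
of one fit's scores varies between fits with coefficient-of-variation roughly
$1/\sqrt{2K}$, and the pooled sd is the root-mean-square of those spreads. A
single term's z-scores therefore have sd slightly below 1 on typical fits,
with the effect shrinking as $K$ grows (at $K = 335$ it is negligible; at the
desk scales used in tests, $K = 30$ keeps the aggregate tail frequency within
the expected band). The null-calibration test uses the generator's null world
(`loading_strength = 0`, `annotation_noise = 1`) where observed labels are
exchangeable with the permutation null by construction.

## Evaluation

Per term: AUC computed as the Mann–Whitney statistic $U/(n_1 n_2)$ with
midrank ties; the two-sided Mann–Whitney test (exact null distribution when
$n \le 20$ without ties, normal approximation with tie-corrected variance and
continuity correction otherwise); Bonferroni flags at strict
$p < \alpha/n_\mathrm{terms}$. Derived precision / sensitivity / F1 columns
use the candidate threshold $z \ge 5$ — the same operating point the
prioritization stage uses; no claim is made that any other threshold was used
elsewhere.

Two networks are compared term by term with the DeLong structural-components
test for correlated AUCs (the same placement-value arithmetic as the AUC
itself, so the AUCs agree bit-for-bit), and "significantly better" applies a
Bonferroni correction over the compared terms by default (`adjust = "none"`
available, since multiplicity handling for this step is a judgment call).
Group summaries add a paired two-sided t-test over per-term AUCs; a
self-comparison reports $p = 1$ with a `zero_difference` flag rather than NaN.

## Patient prioritization

A patient contributes a set of phenotype term IDs and a variant table with a
population maximum allele frequency and a pathogenicity score per variant
(both consumed as inputs; no variant annotation is performed). Per gene, the
per-term z-scores over the patient's terms are combined by Stouffer's
unweighted method $\sum z_i / \sqrt{k}$ (skipping missing terms and reducing
$k$); candidates are the genes with combined $z \ge 5$ (inclusive),
intersected with the genes carrying at least one variant with AF strictly
below 0.005 and score at least 0.0027 (inclusive). These operators are
deliberately literal: the boundary semantics are tested as stated. The
combined-z statistic is reported for all z-passing genes with a
variant-filter flag, so the intersection is auditable.

Cohort-level support for a candidate uses Fisher's exact test on carrier
allele counts (cohort vs reference), via `stats::fisher.test` — its two-sided
rule (summing tables as improbable as the observed one) is the convention we
document. The reported odds ratio is the cross-product ratio
$\frac{a d}{b c}$, not the conditional MLE that `fisher.test` prints, because
the cross-product is what the 2×2 table directly states; a zero denominator
yields an `Inf` sentinel.

## Co-regulation

The co-regulation of two genes is summarized by the Pearson correlation $r$ of
their loading vectors, Fisher-transformed to
$z = \operatorname{atanh}(r)\sqrt{K-3}$. The published score this mirrors is
not formally defined in the literature we follow, so this standard transform
is our documented choice; self-correlation is capped at
$\operatorname{atanh}(1-10^{-15})$ with a warning rather than returning
infinity.

# The synthetic-data generator

`simulate_study()` emulates the statistical structure the method relies on,
not any particular organism's transcriptome:

* counts are negative binomial with a single shared dispersion (default 0.1,
  a typical bulk-RNA-seq value), gene means
  $\exp(\mathrm{base}_g + \sum_f L_{gf} F_{sf})$ with standard-normal factor
  scores;
* ten weak dense background factors plus one strong factor per module
  (default 5 modules × 50 genes, loading 2.0 on the natural-log scale) create
  the co-expression structure;
* tissue-specific modules (by default the last two) have their module loading
  zeroed in the base compendium — the tissue compendium is the only place
  their signal lives, which is exactly the situation the merged network is
  meant to exploit;
* log-normal library sizes (σ = 0.3) give the median-of-ratios stage
  something to correct, and a two-level batch shift (0.5 on the log scale)
  gives the residualization stage something to remove;
* each phenotype term draws its positives from one module, with 10% of labels
  replaced by random background genes (annotation noise), and terms on
  tissue-specific modules are tagged `"tissue_specific"` so grouped
  evaluation works out of the box. Setting `loading_strength = 0` with
  `annotation_noise = 1` yields a fully null study.

What the generator does **not** emulate: realistic mean–variance trends per
gene, gene length or GC effects, correlated annotation errors, ontology
structure between terms, or isoform-level signal. A green test on simulated
data therefore establishes that the machinery recovers the signal it defines —
direction, calibration, and ranking behavior — not that any particular AUC
would be achieved on real compendia.

# Design decisions worth recording

* **Order of normalization.** Size factors are estimated on raw counts and
  applied before the `log2(x + 1)` transform; the median-of-ratios method is
  defined on counts, so the counts-first order is the coherent reading.
* **Provenance-based annotation filtering.** Exclusions for multigenic
  (copy-number) syndromes and mere susceptibility genes are driven by a
  provenance column in the annotation file rather than re-derived from the
  licensed source databases; this keeps the documented filter testable
  offline. Terms keep a configurable minimum of 10 positives — a logistic
  regression on fewer is noise.
* **No ontology propagation.** Annotation files are taken as already
  propagated (the usual distribution format); the parser does not copy genes
  from child to ancestor terms.
* **Exact leave-one-out.** The refit-per-positive is exact rather than an
  influence-function approximation; at tens of positives per term the cost is
  trivial and the anti-leakage guarantee is unconditional.
* **Configuration.** The pipeline takes a single YAML or JSON file mirroring
  the function arguments; all randomness derives from one global seed through
  stage-name-hashed sub-seeds, so stage results do not depend on execution
  order. Every artifact lands in a manifest with md5 hashes; reruns with the
  same config and seed reproduce the hashes exactly.

# Known limitations

* The permutation null refits the model per permutation; at hundreds of
  terms × hundreds of permutations on a 335-component matrix this is the
  dominant cost. The per-term work is embarrassingly parallel but the package
  keeps it single-threaded for determinism.
* z-score magnitudes depend on gene count and component count; thresholds
  tuned at genome scale (like the candidate cutoff of 5) are not directly
  meaningful on very small simulated instances.
* Leave-one-out protects annotated genes from their own label but not from
  their annotated co-module twins; AUCs on densely annotated modules remain
  slightly optimistic relative to a gene-family-holdout design.
* The OLS covariate correction removes linear effects only.
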