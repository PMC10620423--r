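Package: nephronet
Title: Tissue-Aware Gene-Phenotype Prediction Networks from RNA-Seq Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gene-phenotype prediction networks from one or more bulk
    RNA-seq compendia. A processed compendium is decomposed into gene-level
    eigenvector loadings; loadings from a large multi-tissue compendium and a
    smaller tissue-specific compendium are merged and used as features in
    per-phenotype ridge-penalized logistic regressions trained on ontology
    gene-phenotype annotations. Leave-one-out scoring prevents label leakage
    and permutation nulls calibrate per-gene z-scores. The toolkit evaluates
    networks (Mann-Whitney AUC, Bonferroni, DeLong paired ROC comparison),
    prioritizes patient candidate genes by Stouffer-combined z-scores
    intersected with variant filters, tests cohort allele-count enrichment,
    and ships a synthetic-data generator with planted co-expression modules so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
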