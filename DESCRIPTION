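Package: popqtl
Title: Population-Aware cis-eQTL and cis-sQTL Mapping with Fine-Mapping
    and Allelic Fold Change Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping genetic effects on gene expression and
    splicing across globally diverse cohorts. Implements variance
    partitioning of molecular phenotypes across nested population labels,
    permutation-based cis-QTL discovery with beta-approximated gene-level
    p-values, multi-signal fine-mapping by a sum-of-single-effects
    Bayesian regression with purity-filtered credible sets, conditional
    allelic fold change (aFC) effect-size estimation, Weir-Cockerham FST
    and genotype-by-ancestry interaction characterisation of causal
    signals, regulatory-annotation enrichment with matched backgrounds,
    and a fully ground-truthed synthetic cohort generator built on the
    Balding-Nichols allele-frequency model.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
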