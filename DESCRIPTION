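Package: svpopgen
Title: Population-Genetic Analysis of Cohort Structural Variant Callsets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for cohort-scale structural variant (SV) callsets:
    reading and writing SV VCF/BED dialects with symbolic alternate
    alleles; functional-consequence annotation against gene models
    (predicted loss-of-function, copy-gain, intragenic exonic
    duplication); allele-frequency, Hardy-Weinberg, linkage
    disequilibrium, trio-transmission and principal-component
    statistics; Watterson mutation-rate estimation; the adjusted
    proportion of singletons (APS) selection metric with a
    covariate-calibrated neutral reference; gene-level rare-SV
    constraint models; arm-length-normalized ("meta-chromosome")
    positional enrichment; complex-SV allele-structure classification;
    and clinical carrier-frequency screens. A synthetic-cohort
    generator with the statistical structure these analyses assume
    (neutral site-frequency spectrum, Hardy-Weinberg genotypes,
    Balding-Nichols population differentiation, trios, injected
    selection) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    data.table,
    jsonlite,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
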