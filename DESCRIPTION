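Package: ipanet
Title: Integrative Multi-Omics Pathway Enrichment with Network-Based
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Integrates gene-expression and metabolomics pathway
    enrichment into a single bootstrap-normalized score for two-class
    designs. Gene-layer enrichment uses the maxmean gene-set statistic
    with catalog restandardization and class-label permutation;
    metabolite-layer enrichment propagates condition effects through a
    substrate-product reaction network via an influence matrix inside a
    mixed-effects linear model. Per-layer pathway ranks are aggregated by
    stratified bootstrap resampling, combined into a
    variability-normalized score, and outlier pathways are nominated with
    an iterative normal (Grubbs) outlier test. Nominations are validated
    by counting enriched neighbors on the pathway-interaction network and
    comparing against degree-preserving random networks generated by
    double edge swaps. Includes a synthetic two-class multi-omics study
    generator with planted pathway signal, readers and writers for the
    on-disk formats (TSV matrices, GMT memberships, reaction lists), and
    a file-based pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    fgsea,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
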