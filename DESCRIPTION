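Package: pcgaccess
Title: Integrative Analysis of Chromatin Accessibility, Polycomb Marks and
    Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating ATAC-seq chromatin accessibility,
    Polycomb-deposited histone marks (H2AK121ub, H3K27me3) and RNA expression
    across genotypes, as used in Arabidopsis Polycomb-group mutant studies.
    Builds consensus Tn5 hypersensitive sites (THSs) from replicate peak
    calls, quantifies accessibility in CPM over regions, tests feature
    enrichment at THSs with a matched-length Monte Carlo random-region null,
    summarises histone-mark proximity to THSs by distance interval, assigns
    mark peaks to genes via a gene-body/promoter rule, classifies per-gene
    mark levels relative to wild type with an empirical-Bayes moderated
    t-statistic, classifies differential expression, and cross-tabulates mark
    loss, accessibility change and expression change. A synthetic-data
    generator plants known structure at every layer so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    yaml,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
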