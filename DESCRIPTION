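Package: admixfine
Title: Admixture Fine-Mapping and Local-Ancestry Heritability in Two-Way
    Admixed Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for fine-mapping disease loci within regions of admixture
    linkage in two-way admixed populations such as African Americans. Provides
    local-ancestry bookkeeping (majority-vote and nearest-marker imputation
    rules), marker and sample quality control, ancestry-adjusted case-control
    association via logistic estimating equations with cluster-robust
    variance, the affected-only admixture (ADM), ancestry-conditional allelic
    (SNP1), single-causal-variant MIX and DIFF likelihood-ratio statistics
    with unrelated-subsample averaging, pedigree and genotype-based (KING
    robust) kinship with greedy unrelated-subset selection, ancestry- and
    genotype-based relationship matrices with single-component REML and
    liability-scale transformation of heritability, and a synthetic
    admixed-cohort generator so that the full pipeline is testable without
    access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
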