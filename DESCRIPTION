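Package: trnameth
Title: Ageing-Related DNA Methylation Analysis at Human tRNA Gene Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for analysing ageing-related DNA methylation
    at tRNA gene loci from windowed MeDIP-seq methylomes and pooled targeted
    bisulfite sequencing. Provides BED-based tRNA annotation handling with
    blacklist filtering and bedtools-style gene clustering, sliding-window
    methylome representation with CpG density, quantile normalisation,
    per-window linear age models with blood cell-count and batch covariates
    (cross-sectional, twin-subset, longitudinal and mixed-model variants),
    Bonferroni significance thresholds, a CpG-density-matched permutation
    enrichment test with empirical p-values, Fisher's exact enrichment,
    pooled bisulfite coverage QC, pairwise differential methylation with
    region-level p-value combination, and a synthetic-data generator that
    emulates the statistical structure of a twin-cohort blood methylome study
    so the whole pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
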