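Package: methylhet
Title: Spatial and Temporal Intratumour DNA Methylation Heterogeneity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies intratumour DNA methylation heterogeneity on
    Illumina EPIC-style beta-value matrices: copy-number-filtered calling
    of differentially methylated positions (DMPs) between multi-region
    biopsies and between paired primary/relapse tumours, enrichment of
    DMPs across gene-region and CpG-island categories, per-patient
    distance-based minimal-evolution phylogenies with a normal-tissue
    outgroup, SNP-probe sample-identity verification, and association
    statistics (Welch t, Pearson correlation, Cox proportional hazards
    of relapse interval against DMP burden). Includes a synthetic
    EPIC-like cohort generator with known ground truth so every pipeline
    stage can be validated against a recoverable answer, and a pipeline
    orchestrator producing reproducible JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    phangorn,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
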