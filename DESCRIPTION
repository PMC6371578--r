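Package: methylexpr
Title: Integrated Blood DNA Methylation and Gene Expression Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for integrating Illumina 450K-style DNA
    methylation with microarray gene expression in case/control blood cohorts.
    Provides region-aware methylation summarization (TSS1500, TSS200, 5'UTR,
    1stExon, Body, 3'UTR), beta/M-value conversion, moderated differential
    expression and differential methylation with a dual delta-beta decile plus
    FDR criterion, intergenic CpG analysis with enhancer enrichment testing,
    identification of hypo-methylated/upregulated (hypo-up) candidate biomarker
    genes and their dominant methylation-altered regions, and a random-forest
    leave-one-out cross-validated classifier with importance-ranked incremental
    panel selection. A synthetic-cohort generator with planted effects makes
    every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    limma,
    randomForest,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
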