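Package: umivar
Title: Evaluation Framework for UMI-Based Somatic Variant Calling in cfDNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking low-frequency somatic SNV detection in
    deep targeted cell-free DNA (cfDNA) sequencing with unique molecular
    identifiers (UMIs). Provides a seeded synthetic cohort generator (case
    plasma, matched PBMC at whole-exome-like and deep collapsed depths,
    control plasma, and a panel of normals), UMI grouping by the five
    network/exact strategies with quality-weighted consensus calling,
    four per-variant calling statistics (beta-binomial Bayes factors with
    strand-aware AND/OR models, a one-sided Fisher tumor-normal test, a
    TLOD-style likelihood ratio, and a read-feature error-model likelihood
    ratio p-value), PBMC- and panel-of-normals-based filtering rules,
    mutation-level precision-recall benchmarking with VAF stratification,
    tumor-informed and tumor-agnostic sample classification with ROC
    analysis, and sequencing-depth confounder diagnostics with binomial
    downsampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    VariantAnnotation,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
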