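Package: masspipe
Title: Synchronized Containers and Reproducible Pipelines for LC-MS
    Untargeted Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An object-oriented framework for post-peak-table processing and
    analysis of LC-MS untargeted metabolomics data. Provides a
    self-synchronizing dataset container that keeps the feature intensity
    matrix, sample metadata, variable metadata, MS2 spectra and annotation
    results consistent under every operation, while recording each
    processing step (function, parameters, time) for full provenance and
    exact replay. Implements the downstream workflow on top of the
    container: noisy-feature removal, outlier-sample detection, missing
    value imputation, sample-wise and QC-sample-based (LOESS/SVR) drift
    normalization, multi-batch integration, quality-control reporting,
    MS1/RT/MS2 metabolite annotation with MSI confidence levels,
    univariate and multivariate statistics, and hypergeometric pathway
    enrichment. A seeded synthetic-data generator with known ground truth
    makes the entire pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    e1071,
    MASS,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
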