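Package: epiresist
Title: Methylation, Mutation, and Expression Biomarkers of Hypomethylating-Agent
    Response in Relapsed/Refractory AML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying molecular predictors of
    response to hypomethylating agents in relapsed/refractory acute myeloid
    leukemia. Processes restriction-enzyme (DREAM) methylation signature
    counts into filtered, imputed methylation matrices and CIMP-style
    clusters; applies a depth/quality/VAF/annotation filter cascade to
    targeted-panel variant calls and builds binary mutation matrices with
    combined RAS status; computes delta-Ct, per-gene z-scores and the
    four-gene z4 resistance classifier from qPCR triplicates; performs exact
    2x2 association tests, label-permutation differential-methylation
    discovery with empirical p-values, and feature enrichment; and fits
    Kaplan-Meier, log-rank, Cox and logistic models with backward elimination
    and separation handling. Ships a calibrated synthetic-cohort generator
    emulating a resistant subgroup (~20%) with RAS enrichment, CpG-island
    hypermethylation, distinct expression, lower response and shorter
    survival, so the full pipeline is testable without patient data.
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
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
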