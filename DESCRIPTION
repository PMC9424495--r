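Package: thkinetics
Title: Kinetic Transcriptomics of T Helper Cell Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of dense time-course expression data from polarized CD4+
    T helper cell cultures (Th0, Th1, Th2 and the Th1/2 hybrid lineage).
    Detects kinetic genes per condition with a polynomial-regression F-test
    combined with a fold-change rescue rule, clusters temporal profiles into
    kinetic archetypes, calls quantitative and qualitative differentially
    expressed genes via nested F-tests and a correlation-index filter,
    decomposes the hybrid lineage's transcriptome into Th1-like, Th2-like,
    superposition and independent gene programs with a per-gene intercept-free
    linear model, and provides hypergeometric overrepresentation analysis,
    PCA-based bifurcation timing, and a ground-truth synthetic data generator
    for end-to-end validation.
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
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
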