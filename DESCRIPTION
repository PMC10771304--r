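Package: degsig
Title: Integrated Differential Expression Testing and Gene-Signature
    Association for Two-Condition Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for small-sample two-condition expression analysis built
    around an integrated hypothesis-testing caller of differentially
    expressed genes: per-gene t-test, Wilcoxon rank-sum test and a
    median-difference permutation test combined by Stouffer's method,
    Storey q-value multiple-testing correction, and an effect-size filter
    at the 95th percentile of a permutation null of the log2-median-ratio.
    Also provides weighted Z-score gene-signature scoring on
    median-centered standardized expression, stratified Spearman
    association between a driver gene and signature scores, delta-delta-Ct
    relative quantification for qPCR validation, a seeded synthetic-data
    generator with planted differential expression, planted
    driver-signature correlation and planted qPCR fold changes, and a
    reproducible YAML-configured pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
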