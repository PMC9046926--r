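Package: vennfallacy
Title: Interaction Contrasts and False-Negative Enrichment Artifacts in
    Factorial Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to demonstrate and avoid a common fallacy in two-group
    transcriptomics: defining "group-specific" genes as significant in one
    treatment-vs-control comparison but not the other, then running gene set
    enrichment on those lists. Provides a negative binomial GLM differential
    expression engine with per-group and interaction Wald contrasts,
    median-of-ratios normalisation and Cox-Reid adjusted dispersion
    estimation; hypergeometric overrepresentation analysis and the CERNO
    rank-based gene set test; a disco concordance score; t-test power
    arithmetic; and a synthetic count simulator with known ground truth for
    the 2x2 group-by-condition design, used by a replication harness that
    quantifies how false negatives turn shared treatment responses into
    spurious "group-specific" enrichment results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    DESeq2,
    optparse,
    withr
Config/testthat/edition: 3
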