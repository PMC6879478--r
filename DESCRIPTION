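Package: ctpipe
Title: Analysis Pipeline for RT-qPCR Threshold-Cycle Expression Data
Version: 0.1.0
Authors@R: person("ctpipe", "developers", role = c("aut", "cre"),
    email = "ctpipe@example.org")
Description: A five-stage workflow for relative quantification of
    RT-qPCR expression data from threshold-cycle (Ct) reports: parsing of
    vendor tab-separated Ct report dialects, reliability categorization and
    masking of unreliable Ct values, normalization (global mean, modified
    global mean, delta-Ct with geNorm or NormFinder reference-gene
    selection, quantile, and rank-invariant methods), missing-value
    filtering and imputation (KNN, maximum-Ct-plus-one, cubic spline),
    two-group differential expression (t-test, Wilcoxon, rank product with
    permutation-based false-prediction rates), and quality-control
    summaries of per-sample Ct distributions and per-feature coefficients
    of variation. Includes a synthetic Ct data generator and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
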