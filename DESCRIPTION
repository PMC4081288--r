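Package: ctgrid
Title: Primary-Analysis Method Comparison for Single-Cell qRT-PCR Ct Data
Version: 0.1.0
Authors@R:
    person("ctgrid", "developers", email = "ctgrid@example.org", role = c("aut", "cre"))
Description: Tools for primary analysis of nanoscale single-cell qRT-PCR
    cycle-threshold (Ct) matrices: validated Ct input/output with the 999
    missing-reaction code, multicell-control quality regression, three
    data-exclusion strategies (supervised presence cutoff with co-missing
    block detection, reference-gene standard-deviation cutoff with
    limit-of-detection Log2EX transform, all-inclusive), three normalization
    methods (per-cell mean centering, quantile normalization, per-gene
    standardization with plate-effect ANOVA residuals), per-gene modality
    classification (unimodal, bimodal with missing or low-expressor peak,
    trimodal) by AIC model comparison including normal-mixture EM and Johnson
    family fits, Ward and k-means cell clustering with cubic-clustering-
    criterion k selection and optimal-assignment concordance between
    pipelines, per-donor cluster-abundance chi-square tests, and a
    ground-truthed synthetic data generator emulating donor-skewed cell
    subtypes, multimodal genes and plate dropout artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
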