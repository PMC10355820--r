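Package: methdrift
Title: Replication-Driven DNA Methylation Drift Scores from Consensus
    Comethylation Modules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for deriving replication (mitotic) epigenetic drift
    scores from longitudinal cell-passaging DNA methylation data. Builds
    principal-component clocks trained on cumulative population doublings
    with elastic-net component selection, extracts driver CpGs from
    component loadings, constructs consensus comethylation networks
    (biweight midcorrelation, topological overlap, two-dataset consensus)
    to separate physiological replication signal from culture artifacts,
    fits a pooled-PC composite drift score, and evaluates scores with
    covariate residualization, Kruskal-Wallis group tests, Pearson
    correlations, and per-SD Cox proportional-hazard models. Includes a
    synthetic-data generator that plants replication-driven and
    artifact comethylation modules with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
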