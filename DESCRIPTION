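Package: chronomet
Title: Time-Resolved Untargeted Metabolomics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for longitudinal untargeted LC-MS metabolomics
    studies with repeated measures: MS2-score filtering and collapse of
    duplicate features to metabolites, QC stability reporting, paired
    fold-change screening with volcano-style classification and set
    overlaps, fuzzy c-means soft clustering of per-timepoint median
    profiles with minimum-centroid-distance selection of the cluster
    number, correlation-based mapping of cluster centroids to canonical
    temporal patterns, per-metabolite linear mixed-effects trend
    classification with likelihood-ratio tests, cross-group concordance
    selection, and hypergeometric pathway over-representation analysis.
    Includes a synthetic longitudinal study generator with planted
    trajectory archetypes and ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    stats,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
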