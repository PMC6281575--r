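Package: arealscan
Title: Spatial Cluster Detection and Ecological Regression for Areal
    Screening Prevalence Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for small-area spatial epidemiology of
    screening-detected disease prevalence: indirect sex- and
    age-standardisation of case counts, flexibly shaped and circular
    spatial scan statistics with Monte Carlo inference, Tango's C-index
    and the maximised excess events test (MEET) for general spatial
    clustering, univariate offset Poisson ecological regression with
    quartile and trend analyses, and a simulation-based sensitivity
    analysis for screen-positive participants who skipped confirmatory
    testing. Includes a synthetic-data generator producing complete
    municipality-level study bundles with optional embedded elevated-risk
    clusters, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
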