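Package: gorassoc
Title: Association Networks and Demographic Predictors of Female Gorilla Sociality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds yearly and event-anchored proximity association networks from
    focal-animal scan samples of female gorillas, derives Elo-rating dominance
    hierarchies and standardized ranks, assembles individual-year and dyad-year
    model tables with demographic covariates (dependent infant, new immigrant,
    last year in group, new alpha male), and fits hierarchical Student-t models
    and factor-smooth additive models of association strength. Includes a
    synthetic study generator that emulates multi-year, multi-group focal
    sampling with known injected effects for recovery and calibration testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmmTMB,
    mgcv,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
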