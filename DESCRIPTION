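Package: operonoise
Title: Intrinsic Noise Consequences of Operon Cotranscription in Two-Gene Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how cotranscription of interacting bacterial genes
    from one operon reshapes intrinsic gene-expression noise. Provides an
    elementary-step reaction-network representation with exact Gillespie and
    tau-leaping stochastic simulation, linear noise approximation (steady
    state, Jacobian, Lyapunov covariance, normalized covariances and CV2),
    builders for three transcriptional coupling configurations composed with
    six protein-interaction module classes plus a reduced lac-like cascade,
    ultrasensitive-threshold response curves and flux-ratio spike statistics,
    ensemble noise summaries with bootstrap errors, operon-enrichment
    randomization tests and expression-level median-split bootstrap tests,
    and synthetic generators for gene/operon universes, interacting-pair
    tables and single-cell copy-number tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    deSolve
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
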