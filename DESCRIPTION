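Package: mcbead
Title: Two-Step Torsades-de-Pointes Risk Classification from Multi-Channel
    Block at EAD-Generating Concentrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for in-silico cardiac safety pharmacology. Implements
    Hill-equation dose-response arithmetic for multi-ion-channel drug block,
    O'Hara-Rudy-family human ventricular myocyte simulation (original and
    conductance-rescaled variants) with steady-state pacing and pause
    protocols, extraction of action-potential and calcium-transient
    biomarkers, detection of pause-induced early afterdepolarizations (EADs),
    parametric EAD scans over calcium/late-sodium/IKs block space, and a
    two-step torsadogenic risk classifier that gates on the hERG safety
    ratio (IC60,hERG / EFTPC) before logistic regression on channel-block
    features at EAD-generating concentrations. Includes 2D risk maps, a
    ternary risk-map extension, a derived-feature simulation pipeline, and a
    synthetic drug-panel generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
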