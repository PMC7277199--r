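Package: mcrisk
Title: Monte Carlo Estimation of Suicide-Ideation Risk from Psychometric Scales
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores adolescent psychometric instruments (PANSI, family APGAR,
    BSSA-10, BQREB) from item-level questionnaire responses, estimates the
    joint probability density of each (risk factor, suicide-ideation) score
    pair by bivariate Gaussian kernel smoothing, draws samples from that
    density with a Metropolis-Hastings chain, and summarises the retained
    samples as binned joint and conditional probability tables. Includes a
    psychometric validation stage (Kaiser-Meyer-Olkin sampling adequacy,
    Bartlett's sphericity test, Kaiser eigenvalue retention, varimax-rotated
    principal-component loadings) and a Gaussian-copula generator of synthetic
    ordinal questionnaire cohorts so every stage is testable without raw
    study data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
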