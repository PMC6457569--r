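Package: ednaocc
Title: Multi-Scale Occupancy Models for Droplet Digital PCR eDNA Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for inferring species presence from environmental DNA
    (eDNA) surveys quantified by droplet digital PCR (ddPCR). Converts
    droplet counts to absolute concentrations with confidence intervals
    under the Poisson partition model, applies limit-of-blank filtering
    against negative controls, and fits three-level Bayesian occupancy
    models (site occupancy, sample occurrence, PCR-replicate detection)
    with logit-linear covariates by Polya-Gamma Gibbs sampling. Includes
    WAIC model comparison from the site-level marginal likelihood, field
    summaries (temperature imputation, paired-design comparisons), a
    synthetic-data generator with known truth down to droplet counts, and
    a pipeline orchestrator with strict CSV schemas.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
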