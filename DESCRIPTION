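Package: tsce
Title: Two-Stage Clonal Expansion Models of Lung Cancer Incidence with
    Time-Varying Smoking Histories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact piecewise-constant hazard and survival computation for the
    two-stage clonal expansion (TSCE) model of carcinogenesis, with individual
    cigarettes-per-day exposure trajectories reconstructed from
    questionnaire-style smoking records.  Provides left-truncated cohort
    likelihoods, maximum-likelihood fitting with group-structured parameters,
    likelihood-ratio and AIC model selection, Metropolis-Hastings percentile
    intervals, a synthetic-cohort generator emulating the demographic and
    smoking structure of a multiethnic prospective cohort, and incidence /
    relative-risk reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
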