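Package: applause
Title: Social Contagion Models of Audience Applause
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-history models of how applause starts and stops in an
    audience, treated as an SIR-type social contagion. Provides discrete-time
    starting and stopping hazard models driven by global and nearest-neighbour
    social cues, Bayesian model selection by importance-sampled marginal
    likelihood, a stochastic clap-by-clap bout simulator, deterministic
    mean-field differential equations with phase-plane analysis, a synthetic
    study generator with known ground truth, and group-level summary
    statistics including a permutation test of individual consistency.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
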