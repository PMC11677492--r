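Package: hemopd
Title: Population Turn-Over Modelling of Propofol and Remifentanil
    Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-mechanistic population pharmacokinetic-pharmacodynamic
    modelling of mean arterial pressure (MAP) and heart rate (HR) during
    propofol and remifentanil anesthesia. Implements Schnider and Minto
    compartmental pharmacokinetics with plasma- and effect-site
    target-controlled infusion, an indirect-response (turn-over) model of
    MAP and HR with heart-rate feedback and a transient surgical-stimulus
    effect, log-normal inter-individual variability with correlated random
    effects, nonlinear mixed-effects estimation via penalized
    empirical-Bayes fits and a Laplace marginal likelihood,
    prediction-corrected visual predictive checks, subject-level bootstrap,
    and Monte-Carlo simulation of intraoperative hypotension risk.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
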