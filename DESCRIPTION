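Package: cropsens
Title: Global Sensitivity Analysis and Bayesian Calibration for Crop
    Simulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for screening and quantifying parameter sensitivity of
    daily-step crop simulators: Morris elementary-effects screening with
    mu-star/sigma summaries, the extended Fourier amplitude sensitivity
    test (EFAST) for first-order and total-order variance-based indices,
    rank-agreement testing across environments via Savage scores and the
    top-down concordance coefficient, Bayesian calibration of influential
    parameters by random-walk Metropolis sampling with a Gaussian
    likelihood, and model-performance grading on Nash-Sutcliffe/RSR bands.
    Ships a deterministic 21-parameter winter-wheat emulator with a
    single-bucket soil water balance and phase-specific irrigation
    triggers, plus a synthetic arid-site weather generator, so the whole
    workflow runs at desk scale and can be re-pointed at an external
    simulator through a small adapter contract.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
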