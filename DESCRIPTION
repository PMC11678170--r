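Package: secumipd
Title: Model-Informed Precision Dosing of Secukinumab in Plaque Psoriasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population pharmacokinetic/pharmacodynamic modelling and
    model-informed precision dosing (MIPD) of subcutaneous secukinumab in
    chronic plaque psoriasis. Implements a two-compartment pharmacokinetic
    model with first-order absorption and allometric body-weight scaling, an
    indirect-response PASI model with a four-compartment prePASI transit
    chain and a tolerance turnover mechanism, individual Bayesian parameter
    estimation (MAP and Metropolis-Hastings conditional sampling),
    clone-based regimen simulation, probability of PASI <= 1 per candidate
    regimen, regimen optimization/intensification decisions, annual-cost
    arithmetic, prediction-corrected visual predictive checks, and a
    synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
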