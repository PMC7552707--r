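Package: lactomc
Title: Lactate-Based Model Predictive Control of Adherent Cell Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for feeding-strategy design in adherent cell-therapy
    bioprocesses using cumulative lactate as a soft sensor of cell growth.
    Converts sparse daily lactate measurements and medium-replacement logs
    into cumulative input/output trajectories via a dilution mass balance,
    identifies time-varying DARX (dynamic auto-regressive exogenous) models
    linking cumulative replaced medium to cumulative lactate production
    (fixed first-order pole, random-walk b0 coefficient estimated by Kalman
    filtering with fixed-interval smoothing, R2/YIC order selection), and
    runs a receding-horizon model-predictive controller that tracks a
    reference cumulative-lactate trajectory under input and lactate-toxicity
    constraints. A mechanistic logistic-Monod virtual culture plant with
    lactate growth inhibition generates realistic multi-donor, multi-condition
    12-well-plate expansion datasets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
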