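Package: bicea
Title: Cost-Effectiveness Modelling of Bilateral Cochlear Implantation in Children
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-state Markov state-transition model comparing simultaneous
    and sequential bilateral cochlear implantation against bimodal hearing
    (unilateral implant plus contralateral hearing aid) in children with
    severe-to-profound sensorineural hearing loss, from a healthcare payer
    perspective. Provides deterministic cohort-expectation and Monte Carlo
    microsimulation engines with annual cycles, age-banded utility increments,
    time-dependent internal-device failure hazards with warranty logic, an
    incremental resource-use costing layer, ICER computation with dominance
    handling, one-way deterministic sensitivity analysis (tornado), second-order
    probabilistic sensitivity analysis, and cost-effectiveness acceptability
    curves. Includes generators for a synthetic national life table
    (Gompertz-Makeham) and a device-reliability survival curve, plus a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
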