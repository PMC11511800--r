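Package: fallcea
Title: Markov Cohort Cost-Effectiveness Modelling of Fall-Preventive Exercise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Five-state Markov cohort model for the health-economic evaluation
    of digital fall-preventive exercise in community-dwelling people aged 70
    and over. Implements annual transition matrices with an absorbing death
    state, age-adjusted mortality, half-cycle-corrected accumulation of
    quality-adjusted life years and societal costs with discounting,
    application of a fall rate ratio to fall-related transitions, an
    intervention cost ledger, deterministic sensitivity scenarios, and an
    independent microsimulation oracle for validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
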