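Package: neotherm
Title: Multi-State Markov Models for Neonatal Hypothermia Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits three-state continuous-time Markov models to panel-observed
    neonatal hypothermia data (severe/mild/normal axillary-temperature states
    observed on a 30-minute grid), with covariate effects on transition
    intensities, maximum-likelihood estimation, hazard ratios, mean sojourn
    times, AIC and likelihood-ratio model comparison, a Pearson-type
    goodness-of-fit test for panel-observed Markov chains, and an exact
    stochastic simulator of covariate-dependent cohorts emulating the study
    design (scheduled observation, first-hitting stopping, inclusion and
    exclusion filters).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    deSolve,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
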