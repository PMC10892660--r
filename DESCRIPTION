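Package: pbpkddi
Title: Whole-Body PBPK Modeling of CYP3A-Mediated Drug-Drug Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds whole-body, permeability-limited physiologically based
    pharmacokinetic (PBPK) models for rat and human from compound parameter
    tables, couples a victim and a perpetrator drug through competitive
    CYP3A inhibition of intrinsic clearance, and evaluates the predictions.
    Includes in vitro-in vivo extrapolation utilities (substrate-depletion
    half-life to intrinsic clearance, IC50 regression, IC50-to-Ki scaling),
    noncompartmental analysis of concentration-time profiles, model
    performance metrics (mean relative deviation, geometric mean fold
    error, DDI AUC and Cmax ratios, fold classification), Monte-Carlo
    prediction intervals over lognormal virtual populations, local
    sensitivity analysis, and seeded synthetic-data generators for
    virtual PK studies and in vitro assays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
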