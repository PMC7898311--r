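Package: renalpbpk
Title: Physiologically Based Pharmacokinetics in Renal Impairment Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for simulating intravenous pharmacokinetics of renally
    cleared drugs in virtual renal-impairment populations. Generates virtual
    Chinese chronic-kidney-disease cohorts (mild, moderate, severe) from
    recalibrated demographic and physiological equations with Cockcroft-Gault
    glomerular filtration, predicts tissue:plasma partition coefficients by
    the Poulin-Theil and Rodgers-Rowland methods, integrates a whole-body
    perfusion-limited PBPK model with GFR-scaled renal clearance, runs virtual
    trials with non-compartmental analysis, and evaluates predictive
    performance with fold-error and mean absolute prediction error criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
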