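Package: cauticost
Title: Hospital Cost Estimation for Catheter-Associated Urinary Tract Infection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a hospital's annual costs attributable to
    catheter-associated urinary tract infection (CAUTI) from a small set of
    inputs (annual admissions, proportion catheterized, literature-based risk
    and cost parameters), and projects costs and savings after interventions
    that reduce urinary catheter placement and duration. Expected costs follow
    a patient-trajectory factorization (bacteriuria, symptomatic UTI,
    bloodstream infection); duration reductions act on bacteriuria risk
    through a constant-hazard competing-risks closed form. Uncertainty is
    propagated by the delta method with multiplicative (log-scale) confidence
    intervals, cross-checked by Monte-Carlo parameter propagation and a
    patient-level cohort microsimulation. Includes an intervention savings
    grid, tidy() and glance() methods, ggplot2 heatmaps, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
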