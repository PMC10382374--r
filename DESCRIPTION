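Package: fentatwin
Title: Individualized Digital Twins for Transdermal Fentanyl Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates individualized physics-based digital twins of cancer
    patients under transdermal fentanyl therapy. Generates a correlated
    virtual patient population by Gibbs sampling from printed cohort
    summaries, maps each patient's covariates (age, gender, weight, height)
    to a full parameter set for layered-skin Fickian diffusion, a
    five-compartment physiologically based pharmacokinetic model, and
    effect-compartment sigmoid Emax pharmacodynamics for pain (VAS) and
    minute ventilation. Compares conventional 72-hour patch replacement
    against a digital-twin-assisted, pain-feedback-triggered replacement
    policy on population-level pain, plasma-concentration and ventilation
    outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
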