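Package: ibpkin
Title: Dissipation Kinetics and Acute-Toxicity Analysis for Ibuprofen
    Biodegradation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bacterial biodegradation time courses of
    ibuprofen and similar xenobiotics.  Implements three first-order
    disappearance models (simple first-order, biphasic hockey-stick, and
    first-order multicompartment) with closed-form DT50 half-disappearance
    times, bounded nonlinear least-squares fitting to replicate time-course
    data with FOCUS-style adequacy statistics (coefficient of determination,
    scaled error percentage, Pearson chi-square), and automatic best-model
    selection.  A dose-response layer estimates growth-inhibition IC50 and
    bioluminescence-inhibition EC50 by log-linear regression, converts EC50
    to Toxic Units, and assigns Persoone acute-toxicity classes.  A
    synthetic-data generator emulates the triplicate-flask microcosm design
    (28-day sampling, additive and proportional noise, detection limits,
    LOQ-censored metabolite series) so that every analysis stage can be
    exercised and validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
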