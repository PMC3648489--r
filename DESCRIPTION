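Package: tqtcross
Title: Design and Analysis of Thorough QT Trials with a Replicated
    Placebo Crossover Design
Version: 0.1.0
Authors@R:
    person("TQT", "Maintainers", email = "maintainers@tqtcross.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing thorough QT/QTc (TQT)
    trials that use a five-period Williams crossover with two placebo
    periods in place of the conventional four-period single-placebo
    layout.  Provides Williams-square generation with a placebo-placement
    constraint, blocked randomisation, session accounting, analytic and
    Monte Carlo power against the 10 ms regulatory margin, a synthetic
    trial-data generator (triplicate ECGs driven by a one-compartment
    pharmacokinetic profile), heart-rate correction of the QT interval
    (Bazett, Fridericia, individual and population exponents), the
    crossover ANCOVA for placebo-corrected change from baseline,
    by-timepoint repeated-measures contrasts, assay-sensitivity and
    categorical outlier analyses, noncompartmental pharmacokinetics
    (Cmax, tmax, linear-up/log-down AUC), and linear concentration-QTc
    exposure-response modelling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
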