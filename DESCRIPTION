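Package: htcue
Title: Cost-Utility Analysis of Hypertension Blood-Pressure Screening Strategies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A nine-state annual-cycle Markov cohort model for cost-utility
    analysis of blood-pressure screening strategies (clinic measurement, home
    measurement, and two serial clinic-then-home protocols). Composes serial
    diagnostic test performance from component sensitivities and
    specificities, accrues lifetime discounted costs (screening, direct
    medical, direct non-medical), life years and quality-adjusted life years,
    and compares strategies via incremental cost-effectiveness ratios,
    dominance classes and net monetary benefit. Includes model calibration to
    age-band hypertension prevalence targets, one-way (tornado) and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves, and a synthetic parameter-set generator emulating the structure of
    a full calibrated input table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
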