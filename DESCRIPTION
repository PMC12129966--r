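Package: icutrigger
Title: Trigger-Based Active Surveillance of Adverse Drug Reactions in Intensive Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An adapted Global Trigger Tool pipeline for active pharmacovigilance
    in intensive care units. Scans structured patient records (demographics,
    time-stamped laboratory results, medication courses and administrations,
    clinical note events) against a 28-trigger catalog spanning medication,
    care and laboratory modules; adjudicates adverse drug reactions with
    Naranjo and WHO-UMC causality, WHO severity and Rawlins-Thompson mechanism
    classifications plus ATC drug coding; scores per-trigger performance
    (rates per 100 records and positive predictive value); summarises organ
    failure with SOFA scores; and models ADR risk factors with group
    comparisons and stepwise logistic regression. Ships a calibrated synthetic
    two-unit ICU cohort generator with embedded ground-truth reactions so the
    whole pipeline is testable without access to hospital charts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
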