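Package: mmlot
Title: Line-of-Therapy Derivation and Economic Burden Analysis for
    Multiple Myeloma from Administrative Claims
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing treatment patterns and health care
    resource utilisation (HCRU) of newly diagnosed multiple myeloma (MM)
    patients from pseudonymised administrative claims, modelled on the
    structure of the French national claims database (SNDS). Provides
    cohort construction (diagnosis confirmation, index date, eligibility
    and exclusion rules, follow-up determination), algorithmic
    line-of-therapy (LOT) segmentation of drug dispensing streams using
    regimen windows, per-drug grace periods and discontinuation gaps,
    Charlson comorbidity scoring from ICD-10 claims, cost aggregation with
    MM-attribution rules (per-patient-per-year and per-patient-per-month
    rates, event-of-interest hospitalisation accounting), report table
    renderers, and a seeded synthetic claims generator with ground-truth
    treatment trajectories so that every pipeline stage is testable
    without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
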