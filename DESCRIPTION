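Package: acsstrial
Title: Design and Simulation Toolkit for Symptom-Scored Cystitis Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing randomised trials
    that compare non-antibiotic with antibiotic treatment of uncomplicated
    acute cystitis (uAC) in women, using the Acute Cystitis Symptom Score
    (ACSS) as the patient-reported outcome measure. Implements ACSS domain
    scoring and nested symptom-set variants (EMA three-symptom, FDA
    four-symptom, ACSS five- and six-symptom), symptom/pyuria eligibility
    rules, species-aware bacteriuria significance policies, visit-window
    classification with cure/failure adjudication under competing score
    thresholds, a diagnostic-accuracy metric battery (sensitivity,
    specificity, likelihood ratios, diagnostic odds ratio, Youden index,
    AUC), risk-difference non-inferiority analysis with Newcombe hybrid
    score intervals, and a seeded synthetic-cohort generator so that every
    pipeline stage is exercisable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
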