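Package: afscreen
Title: Cost-Effectiveness Microsimulation of Wearable-Based Atrial
    Fibrillation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level Markov Monte-Carlo simulation of screening for
    atrial fibrillation (AF) with photoplethysmography (PPG) wrist-worn
    devices, from the perspective of statutory health insurance. Simulated
    patients, stratified by CHA2DS2-VASc score, move through annual cycles
    of AF onset, device-based and standard-care detection, anticoagulation
    therapy, stroke, bleeding and death. The package derives all model
    parameters from published rates, prices each patient-year in discounted
    euros, and compares device and no-device arms in terms of average cost
    per patient, prevented strokes and cost per prevented (fatal) stroke,
    including one-way sensitivity grids over device accuracy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
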