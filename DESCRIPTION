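Package: hearscreen
Title: Simulation and Diagnostic Validity of Hearing-Scale Screening for
    Sudden Sensorineural Hearing Loss
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates smartphone-based hearing screening with the stratified
    Hearing Scale Test (20 scales, 5 dB apart) against conventional pure-tone
    audiometry. Provides a psychometric virtual-listener model, the adaptive
    scale-search engine, a modified Hughson-Westlake threshold procedure,
    device-calibration staircases (ascending 1-dB search and 2-down/1-up),
    the triage and referral workflow for sudden sensorineural hearing loss
    (SSNHL), a seeded synthetic-cohort generator, and diagnostic-validity
    statistics (sensitivity, specificity, predictive values with exact
    Clopper-Pearson intervals, Fisher-z correlation intervals, and
    reconstruction of integer contingency tables from rounded percentages).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
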