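Package: ipindex
Title: Integrated Pulmonary Index from Capnography and Pulse Oximetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the Integrated Pulmonary Index (IPI), a Mamdani
    fuzzy-logic fusion of end-tidal CO2, respiration rate, oxygen
    saturation and pulse rate into a single 1-10 respiratory-status
    score, for adult and pediatric modes. Includes threshold-duration
    detectors for severe and clinically significant respiratory events
    (apnea, hypoxia, hypoventilation), an overlapping-epoch reliability
    analysis (sensitivity, specificity, ROC/AUC per IPI threshold), a
    seeded generator of synthetic vital-sign streams with ground-truth
    event bookkeeping, and a command-line interface for reproducible
    runs on CSV recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
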