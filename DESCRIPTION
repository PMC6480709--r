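Package: dynaverify
Title: Treatment Delivery Verification from Varian MLC Dynalog Files
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for patient-specific quality assurance of dynamic
    radiotherapy deliveries from the log files written by the Varian
    multi-leaf collimator (MLC) controller. Parses dynalog bank-file
    pairs, reconstructs deliverable VMAT plans from expected or actual
    leaf positions (uniform, per-segment, and error-detecting sampling),
    magnifies recorded leaf-position errors for sensitivity studies, and
    quantifies agreement between three-dimensional dose distributions
    with the dose-volume-histogram percentage of agreement, the gamma
    pass rate, leaf-error RMS statistics, and systematic-difference
    (alpha/delta) analysis. Includes a deterministic toy dose engine and
    a synthetic-data generator so the whole pipeline can be exercised
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
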