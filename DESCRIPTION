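Package: lotqa
Title: Leaf-Open-Time Attainment Analysis for Helical Binary-MLC Deliveries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates planned and telemetry-measured leaf-open-time (LOT)
    sinograms for helical tomotherapy deliveries with a 64-leaf binary
    multileaf collimator, builds LOT and difference histograms, and computes
    the LOT attainment rate (the fraction of planned leaf openings whose
    measured-minus-planned timing difference falls in the zero bin).
    Includes cohort-level aggregation with box-plot IQR outlier screening,
    Spearman rank correlation with five-level strength classification,
    Welch's t-tests of site means against the pooled cohort, and
    detector-signal/attainment co-decline trend flagging, together with
    strict CSV/JSON interchange for reproducible runs.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
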