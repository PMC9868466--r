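Package: p4valid
Title: Immunoassay Method Validation for Cattle Progesterone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytical validation of quantitative immunoassays, built around a
    cattle serum/plasma progesterone spike-and-recovery design. Provides
    within-run and between-run precision profiling with coefficient-of-variation
    trendlines, spiking-recovery bias, detection limits (limit of blank,
    detection and quantification), reportable-range linearity assessment,
    interlaboratory method comparison by Passing-Bablok regression and
    Bland-Altman limits of agreement with concentration-binned bias, and
    observed total analytical error (Westgard) in its spiking-recovery,
    range-based and average-based variants. Includes a synthetic-data generator
    that emulates the replicate spike panels, quality-control panels and paired
    two-laboratory datasets the protocol consumes, so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
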