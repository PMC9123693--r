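Package: detachr
Title: Non-Wear Detection for Wrist-Worn Accelerometer and Temperature
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects periods during which a wrist-worn accelerometer was not
    being worn, by combining the rate-of-change of the device's near-body
    temperature with per-axis rolling standard deviations of tri-axial
    acceleration (the DETACH rules), alongside re-implementations of the
    van Hees acceleration-only and Zhou combined temperature-acceleration
    comparator algorithms.  Includes EDF and CSV recording input/output, a
    second-resolution evaluation harness (confusion matrices, precision,
    recall, F1, accuracy with per-participant aggregation), a synthetic
    recording generator with exact ground truth for validation, and
    depth-limited CART threshold discovery utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
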