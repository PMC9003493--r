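Package: sipwise
Title: Sip Detection and Fluid-Intake Estimation from Smart-Bottle Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale implementation of an on-device hydration monitoring
    pipeline for instrumented water bottles. Detects drinking gestures (sips)
    from single-axis accelerometer time series via moving-average filtering,
    peak segmentation, range normalization and fixed-length episode windows;
    classifies episodes with a minimal fully connected neural network trained
    from scratch; detects first sips after bottle refills from sip-height
    gradient features; and estimates cumulative fluid intake with a
    self-correcting volume algorithm that snaps each drinking cycle onto an
    integer number of bottle volumes. Includes a seeded synthetic
    drinking-session simulator so every stage is testable without sensor
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
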