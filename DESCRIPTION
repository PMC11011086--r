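Package: dogsleep
Title: Automated Sleep Scoring of Kennelled Dogs from Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scores sleep in kennelled dogs from fixed-camera video.
    Per-frame dog detections (from a pluggable detector or synthetic ground
    truth) are cropped and passed through a six-step frame-differencing
    motion detector (grayscale conversion, Gaussian blur, inter-frame delta,
    thresholding, dilation, connected-component area); windows without
    detected movement are scored as sleep.  The package segments the
    resulting state sequences into sleeping bouts, summarises sleep duration
    and fragmentation per session, reads BORIS-style behavioural observation
    logs so human and automated scores share one comparison path, and
    provides the method-agreement statistics (frame-level agreement,
    Anderson-Darling normality, paired t-tests) used to validate automated
    scoring against human observation.  A seeded synthetic-scenario
    generator renders blob dogs with known sleep/wake schedules, day and
    night camera modes, and nuisance effects (camera shake, light flicker,
    sensor noise) so the whole pipeline is testable without real footage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    nortest,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
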