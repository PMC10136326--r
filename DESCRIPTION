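Package: wearseiz
Title: Semi-Automated Multimodal Seizure Detection from Wearable EEG and ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for semi-automated seizure detection from two-channel
    behind-the-ear EEG (bte-EEG) and single-lead ECG recordings. Implements a
    sliding-window bte-EEG detector (2 s windows, 67 features, RBF support
    vector machine, 8-of-10 post-processing), a heart-rate based ECG detector
    (R-peak ensemble, 60 s windows, minimum 60 s events), late 'OR' fusion of
    the two alarm streams, event-based performance scoring (sensitivity,
    false detections per 24 h, PPV, F1), inter-rater statistics (Cohen's
    kappa, McNemar's test), and a review-workflow exporter for human
    relabelling of alarms. A seeded synthetic-recording generator produces
    bte-EEG background with ictal rhythmic bursts, artifact episodes, and ECG
    with configurable peri-ictal heart-rate profiles, so the full pipeline is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
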