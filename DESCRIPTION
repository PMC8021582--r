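Package: seegwatch
Title: Self-Supervised Seizure Anomaly Detection for SEEG and Video Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-specific, label-free seizure detection for epilepsy
    monitoring units. Per-channel sequence forecasters (a compact LSTM or an
    autoregressive baseline) are trained on the opening minutes of a
    stereo-EEG recording; smoothed forecast errors are classified by a
    nonparametric dynamic threshold with anomaly pruning and compared against
    a conventional static threshold. A convolutional-LSTM autoencoder turns
    bedside video frames into a regularity-score series that feeds the same
    detection path, and detections from both modalities are pooled and scored
    event-wise (PPV, sensitivity, F1, MAPE) against labelled intervals. A
    seeded synthetic-data generator emulates ictal spike-wave discharges,
    drifting background noise, and video regularity traces so the whole
    pipeline is testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
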