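Package: trainload
Title: Training Efficiency and Load Balance Assessment from Wearable Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for assessing weightlifting training sessions from
    wrist-worn inertial sensors and a heart-rate monitor. Continuous
    two-wrist inertial streams are segmented into fixed-length overlapping
    windows, summarised by six time-domain statistics per channel, and
    classified into four lift phases (grip, lift-off, clean-and-jerk,
    set-down) with a random forest. Phase durations yield an effective
    training rate; relative heart rate drives a linear Borg-RPE fatigue
    model; the two ratings are fused into a nine-state session assessment
    with management recommendations. Includes a synthetic session generator
    so the full pipeline is testable without device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
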