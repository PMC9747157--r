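Package: stimtune
Title: Stimulus-Triggered Averaging of EMG and Torque During Directional Motor Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and quantify post-stimulus effects (facilitation and
    suppression) in stimulus-triggered averages (StTAs) of rectified EMG recorded
    during a directional isometric torque task, to characterize their directional
    tuning against voluntary torque direction (preferred directions by vector
    summation with shuffle-based significance, circular statistics), to relate
    effect magnitude to background EMG level, and to extract evoked wrist-torque
    vectors from detrended torque StTAs. Includes a synthetic-session generator
    with closed-form oracles for validation, and an end-to-end pipeline with
    deterministic seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
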