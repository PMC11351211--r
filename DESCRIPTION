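Package: gaitdgei
Title: Dynamic Gait Event Identification from Single-Channel IMU Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Real-time detection of heel-strike, toe-off, walking-start and
    walking-pause events from a single shank-mounted inertial sensor channel.
    Implements the Dynamic Gait Event Identifier: positive and negative
    sliding-window integrals of weighted first differences, an adaptive
    refractory ("sleep time") period driven by a weighted FIFO queue of
    recent stride intervals, and an adaptive amplitude threshold derived
    from recent accepted peak magnitudes. Includes frame-tolerance event
    matching with sensitivity, mean absolute deviation and Matthews
    correlation coefficient, a seeded synthetic gait-signal generator with
    ground-truth annotations, a hyperparameter grid-search tuner, and CSV
    readers and writers for signals, events and configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    parallel,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
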