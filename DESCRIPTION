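Package: inactivityscore
Title: Inactivity-Based Emergency Detection from Uncertain Smart-Home Sensor Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects emergencies (abnormally long inactivity) in single-occupant
    smart homes from timestamped binary activity-sensor events whose detections
    carry per-sensor certainty values. Implements the Inactivity Score, a
    recursive score that grows linearly with elapsed time and is multiplied at
    each activity event by a certainty-weighted reduction factor with a
    time-decayed sensor impact, together with a weekend-aware, IQR-clipped
    adaptive threshold rule for raising alarms. Includes readers for
    CASAS-style event logs, a circadian event-stream simulator with
    truncated-normal sensor certainties and matched spurious-event noise sets,
    and an evaluation harness measuring false-positive rates and detection
    latency for simulated emergencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    zoo,
    withr
Config/testthat/edition: 3
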