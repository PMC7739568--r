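Package: skiturn
Title: Gyroscope-Based Turn Detection for Alpine Skiing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects turn switch points, turns and turn sequences in alpine
    skiing from the roll-axis angular velocity of two boot-mounted gyroscopes.
    The bilateral mean roll rate is low-pass filtered with a fourth-order
    zero-lag Butterworth filter to form a decision signal whose local extrema
    are candidate turn switches; a set of heuristic labeling rules plus a
    two-threshold elimination rule classifies each extremum as a turn switch,
    within-turn noise, or an artifact to be eliminated, and switch timestamps
    are refined on a 3 Hz fine-tuning signal. Includes event-matching
    evaluation metrics (ratio, turn-count precision, recall) with a
    half-mean-turn-duration time tolerance, and a seeded two-boot signal
    simulator that generates carved, drifted, snowplow, stop and straight
    gliding segments with exact ground-truth switch times for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
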