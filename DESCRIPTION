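Package: physcap
Title: Sensor-Based Assessment of Physical Capability from Lumbar IMU Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the 73 inertial-sensor measures that characterise three
    instrumented functional tests for older adults -- 30 s quiet standing,
    a 7-meter walk and the 5-times chair stand -- from smartphone-style
    lumbar accelerometer and gyroscope recordings, and condenses them into
    a conceptual model of physical capability by exploratory factor
    analysis (parallel-analysis factor retention, varimax rotation,
    loading-based measure assignment, Thurstone regression factor scores).
    Includes construct-validity statistics (covariate-adjusted linear
    associations, Bland-Altman agreement of durations), percentile-based
    radar profiles, and a synthetic-data module that simulates sway, gait
    and chair-stand recordings, factor-structured feature matrices and
    cohort tables so the whole pipeline runs without access to clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
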