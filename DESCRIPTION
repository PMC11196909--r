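Package: activityspace
Title: GPS Activity-Space and Behavior-Location Analysis for Mobile Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes individual activity-space measures from smartphone GPS
    logs collected in mobile-health cohort studies: average great-circle
    distance traveled per week, unique locations visited (greedy 25-m
    deduplication), and the percentage of GPS fixes outside circular home
    buffers (100/400/800 m). Links time-stamped ecological momentary
    assessment behavior reports to GPS fixes by nearest timestamp and counts
    unique behavior locations and reports away from home. Aggregates
    per-participant measures into cohort median/IQR/range tables, and ships a
    synthetic-cohort generator with exact ground truth so every pipeline
    stage is testable without participant data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    lubridate,
    readr,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
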