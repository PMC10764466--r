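Package: chaoscope
Title: Auditory Household-Chaos Classification from Daylong Infant-Worn Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring auditory household chaos from daylong
    child-worn audio. Segments recordings into 5-second units, computes
    sliding-window acoustic features (RMSE, spectral flatness, MFCCs,
    log-mel spectrograms), triages rare high-chaos segments for annotation
    with a sound-event-prediction based detector (class grouping, pruning
    heuristics and a participant-normalised loudness override), and trains
    and evaluates three 4-level chaos classifiers: a volume-only random
    forest baseline, a 53-feature acoustic random forest, and a compact
    pre-activation convolutional network over log-mel patches with
    geometric-mean patch aggregation. Includes leave-one-participant-out
    cross-validation with class-balanced training-set construction,
    macro/weighted metrics, paired model comparison, a data-ablation
    harness, and a seeded synthetic soundscape generator so the full
    pipeline is testable without access-restricted home recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    ranger,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
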