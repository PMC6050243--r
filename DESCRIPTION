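Package: spitrain
Title: Inter-Pulse-Interval Statistics and Playback Preference Analysis for
    Mormyrid Electric Pulse Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the timing of electric organ discharges
    (EODs) in weakly electric fish. Reads pulse-timestamp trains, computes
    inter-pulse-interval (IPI) sequences, 2-ms IPI histograms and
    five-variable sequence summaries (total EODs, runs, mode IPI, interval
    range), serial correlograms with a permutation-derived chance level and
    the serial-correlation duration, PCA of log-transformed feature tables,
    and strength-of-preference (SOP) statistics for two-choice playback
    experiments. Includes calibrated synthetic pulse-train generators
    (renewal, sticky-state semi-Markov, AR(1) log-interval) for testing
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    lme4,
    lmerTest,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
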