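Package: oddvol
Title: Auditory Oddball Sound-Level BCI Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for auditory oddball
    brain-computer interface (BCI) experiments that manipulate sound
    pressure level. Generates synthetic multi-channel oddball EEG with
    P300-like target responses, loudness-dependent amplitudes,
    habituation across sessions and 1/f background noise; preprocesses
    continuous recordings (startle-trial removal, Butterworth band-pass,
    epoching, baseline correction, decimation, vectorization); computes
    condition-average event-related potentials, 20-ms block amplitudes
    and Wilcoxon signed-rank significance maps; classifies target versus
    nontarget trials with a linear soft-margin support vector machine
    under nested cross-validation with pseudorandom trial averaging and
    balanced accuracy; and aggregates study-level accuracy tables,
    Friedman and paired Wilcoxon tests, half-session habituation deltas
    and the Wolpaw information transfer rate. Includes European Data
    Format (EDF) and tab-separated event-table readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
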