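Package: photoddball
Title: Fiber-Photometry Dopamine Responses to Auditory Deviance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying phasic dopamine signals recorded with
    two-channel fiber photometry during auditory deviance paradigms.
    Generates the stimulus paradigms of the auditory oddball /
    many-standards family (single and brief presentations, duration and
    intensity-change series, repetitive trains, oddball sequences with
    run-length constraints and role swap, many-standards control),
    converts raw excitation/isosbestic fluorescence to delta-F/F via
    isosbestic regression, z-scores globally or in local peri-event
    windows, extracts event-aligned epochs and multi-component response
    features (onset-positive, onset-negative, intra-stimulus dip,
    offset-positive, drop-positive, peak-to-trough), computes
    place-preference behavioral metrics, and provides the matching
    statistics (exact Wilcoxon signed-rank, Friedman with Conover post
    hoc, JZS Bayesian paired t-test, Spearman correlation). A
    synthetic-data module simulates two-channel recordings with a known
    dopamine kernel, sensor kinetics, photobleaching and shared
    artifacts, plus behavioral sessions, so that every stage of the
    pipeline can be validated by parameter recovery and statistical
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    scales,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
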