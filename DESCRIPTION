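Package: pafscreen
Title: Rule-Based Paroxysmal Atrial Fibrillation Screening from RR Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects paroxysmal atrial fibrillation (PAF) episodes in long-term
    ECG from beat-to-beat (RR) interval irregularity. A short-window rhythm-change
    statistic (standard deviation over mean of six adjacent RR intervals) screens
    suspicious segments, and a rejection cascade removes the premature-beat
    rhythms that mimic AF: single premature beats via a run-length rule, frequent
    premature beats and bigeminy/trigeminy via K-medoids clustering of RR features
    followed by rhythm re-screening of the selected interval group. Includes a
    synthetic rhythm generator (normal sinus rhythm, AF, ectopy patterns, optional
    ECG waveform rendering), ECG pre-processing (baseline removal, signal-quality
    gating, QRS detection and refinement), a WFDB record/annotation reader and
    writer, an episode-boundary evaluation framework (PAF-score, error and missed
    segments, beat-level sensitivity and specificity), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    cluster,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
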