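Package: pupilEffort
Title: Pupillometry-Based Listening Effort Analysis for Adaptive
    Speech-in-Noise Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring listening effort from task-evoked
    pupillometry recorded during adaptive speech-in-noise (HINT-style)
    testing, aimed at cochlear-implant and hearing-device research.
    Provides an event-related pupil preprocessing chain (resampling to a
    uniform 60 Hz grid, median-absolute-deviation blink detection with
    pre/post margins, standard-deviation outlier and short-island removal,
    gap interpolation, moving-average smoothing), baseline-corrected
    epoching and peak pupil dilation (PPD) extraction, a one-up/one-down
    adaptive staircase simulator over logistic psychometric listeners, a
    repeated-measures statistical battery (within-subject ANOVA with a
    pooled error stratum, Shapiro-Wilk residual checks, Games-Howell post
    hoc comparisons, Bonferroni thresholds, Spearman rank correlation with
    exact small-sample p-values), and a synthetic-data generator so the
    full pipeline can be exercised and validated end to end without access
    to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
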