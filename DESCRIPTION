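Package: arousalstrat
Title: EEG Vigilance Staging and Arousal-Based Stratification of Fatigue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for stratifying fatigued patients by brain
    arousal regulation from resting eyes-closed EEG. Classifies 1-s EEG
    segments into seven vigilance stages from spectral content, slow eye
    movements and sleep graphoelements; summarises each recording into an
    arousal stability score (1-11) and splits subjects into hypoaroused
    and non-hypoaroused groups; scores the MFI-20, BDI-II, ESS, SSS and
    SF-A/R questionnaires with missing-item rules; and runs the
    nonparametric group-comparison battery (tie-corrected Mann-Whitney Z,
    Pearson chi-square, Spearman and partial rank correlation, eta-squared
    effect sizes with percentile-bootstrap confidence intervals). Includes
    a synthetic-data module that simulates multichannel EEG with scripted
    vigilance trajectories and cohort questionnaire tables, plus readers
    and writers for BrainVision and EDF recordings and the pipeline's
    tabular artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
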