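Package: brseeg
Title: Between-Run Spectral-Power Similarity Analysis of Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies task-induced intra-subject variability of resting-state
    EEG as a between-run similarity (BRS) of spectral-power vectors, and
    provides the analysis pipeline built around that statistic: recording
    ingestion (EDF or plain array files), FIR band-pass filtering, overlapping
    epoch segmentation with amplitude-based epoch rejection, per-epoch
    band-power extraction, scalp-region power vectors, raw and
    healthy-control-standardized BRS, single-run comparison features (spectral
    power, Katz fractal dimension, band coherence), LDA and RBF-SVM
    classification under leave-one-participant-out cross-validation with
    sequential forward selection and grid search, nonparametric group
    statistics with Bonferroni control, and a synthetic two-run cohort
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'brseeg-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'montage.R'
    'bands.R'
    'recording-io.R'
    'preprocess.R'
    'bandpower.R'
    'baselines.R'
    'brs.R'
    'classify.R'
    'simulate.R'
    'stats.R'
    'tables.R'
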