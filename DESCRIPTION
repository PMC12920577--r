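Package: leadnet
Title: Lead-Graph and Transformer Classification of Holter ECG Arrhythmias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for multi-lead ambulatory (Holter) ECG
    arrhythmia detection. Reads WFDB-style and delimited ECG recordings,
    simulates labelled multi-lead recordings with class-dependent beat
    morphology and realistic noise, preprocesses signals (zero-phase
    Butterworth bandpass, min-max normalization, overlapping sliding-window
    segmentation, label encoding), extracts time-domain, frequency-domain and
    non-linear heart-rate-variability features (SDNN, Poincare SD1/SD2,
    approximate entropy, VLF/LF/HF band powers), and classifies fixed-length
    segments with a hybrid model: graph convolution over the ECG leads fused
    with a transformer encoder over time, trained with Adam and cross-entropy.
    Includes stratified/grouped cross-validation, grid search, a full metric
    suite (confusion matrix, per-class precision/sensitivity/specificity/F1,
    FNR/FPR, one-vs-rest ROC-AUC), ablation runners, paired t-tests, and
    clinical-alert mitigation tools (per-class decision thresholds, temporal
    alert aggregation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
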