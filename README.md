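# leadnet

Arrhythmia detection on multi-lead ambulatory (Holter) ECG with a hybrid
lead-graph / transformer classifier, packaged as a complete, testable R
pipeline: signal I/O, a seeded synthetic Holter generator, preprocessing,
heart-rate-variability feature extraction, the model itself (with its own
training machinery), and a full evaluation and clinical-alert toolkit.

## Who this is for

Researchers and engineers prototyping segment-level arrhythmia classifiers
over the four beat-class alphabet **N** (normal), **S** (supraventricular),
**V** (ventricular), **E** (ectopic), who want every stage reproducible from
a seed and runnable on a laptop without downloading clinical data. The
built-in generator produces labelled multi-lead recordings with
class-dependent beat morphology (sum-of-Gaussians P-QRS-T), prematurity,
baseline wander, powerline and white noise, so the whole pipeline is
exercisable end to end.

## The method

1. **Preprocessing.** Zero-phase fourth-order Butterworth bandpass
   (0.5–40 Hz), per-segment min–max normalization
   `x_norm = (x − min x)/(max x − min x)`, sliding-window segmentation into
   Δt = 10 s windows with 50% overlap (stride 5 s; N = fs·Δt samples, e.g.
   3600 at 360 Hz), and integer label encoding with severity-priority
   window labelling (V ≻ S ≻ E ≻ N).
2. **Features.** Per segment, per lead, per 1 s sub-window: RR statistics
   from Pan–Tompkins-style R-peak detection (mean RR, SDNN, mean HR, beat
   count), periodogram band powers `PSD(f) = |FFT(x)|²` with LF/HF ratio
   and dominant frequency, approximate entropy ApEn(m = 2, r = 0.2σ),
   Poincaré SD1/SD2, and amplitude moments — 14 features plus
   observed-value masks.
3. **Model.** Per sub-window, graph convolution over the lead graph
   `h_v' = σ(Σ_{u∈N(v)} c_vu⁻¹ W h_u + b)` with c_vu = √(deg v · deg u);
   lead mean-pool; linear embedding plus sinusoidal positional encoding;
   transformer encoder blocks with scaled dot-product multi-head attention
   `softmax(QKᵀ/√d_k)V`, add & layer-norm, feed-forward; temporal
   mean-pool; ReLU fully connected layer and softmax
   `ŷ = softmax(W_o h_final + b_o)`. Trained with Adam on (optionally
   class-weighted) cross-entropy. Forward, backward and optimizer are
   implemented in vectorized base R and verified against finite
   differences.
4. **Evaluation & mitigation.** Confusion matrix; per-class
   precision/sensitivity/specificity/F1/FNR/FPR with macro, micro and
   support-weighted aggregates; one-vs-rest rank-statistic ROC-AUC;
   stratified and patient-level cross-validation; grid search; ablations
   (GNN-only, transformer-only, uniform attention, feature subsets);
   paired t-tests; per-class decision-threshold optimization and temporal
   alert aggregation (alert only after k consecutive abnormal segments).

## Worked example

```r
library(leadnet)

# simulate a 6-patient cohort and build the model-ready dataset
cohort  <- make_cohort(n_patients = 6, duration = 420, fs = 125, seed = 3)
dataset <- build_dataset(cohort)           # filter -> segment -> label -> features
dim(dataset$x)
#> [1] 498  10   2  28                      # segments x sub-windows x leads x channels

# patient-level hold-out, compact model, 15 epochs
res <- run_pipeline(seed = 3, dataset = dataset)
res$metrics
#> metrics_report on 166 samples: accuracy 0.9458, macro F1 0.9459
#>   class support precision sensitivity specificity     f1    fnr    fpr
#> 1     0      22    0.9565      1.0000      0.9931 0.9778 0.0000 0.0069
#> 2     1      50    0.9615      1.0000      0.9828 0.9804 0.0000 0.0172
#> 3     2      38    0.8919      0.8684      0.9688 0.8800 0.1316 0.0312
#> 4     3      56    0.9630      0.9286      0.9818 0.9455 0.0714 0.0182
round(res$auc$macro, 3)
#> [1] 0.989
```

(Accuracy on this small 6-patient example is ~0.95; the reference
12-patient benchmark reaches ~0.97, see below.) The per-class rows are the
one-vs-rest counts and rates for E, N, S, V in label-code order; `fnr` is
the per-class miss rate, the costliest error for a monitoring alarm.

Shell interface over the same functions:

```sh
Rscript inst/exec/leadnet simulate --config sim.yaml --seed 3 --out sim/
Rscript inst/exec/leadnet pipeline --seed 7 --out run/
```

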