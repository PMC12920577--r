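---
title: "leadnet: methods, modelling choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{leadnet: methods, modelling choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
open design decisions were resolved the way they were. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem

Ambulatory (Holter) ECG produces hours of multi-lead signal in which
clinically important arrhythmic episodes — supraventricular (S),
ventricular (V) and other ectopic (E) activity against a normal (N)
background — are sparse and morphologically varied. The package classifies
fixed-length signal segments into these four classes and converts segment
streams into clinical alerts. Spatial structure (the relation between
leads) is modelled by a graph neural network over the lead graph; temporal
structure (the evolution across sub-windows of a segment) by a transformer
encoder.

## Preprocessing

* **Bandpass 0.5–40 Hz, Butterworth order 4.** The low edge removes
  baseline wander and motion artifact, the high edge muscle noise and
  powerline interference. The filter is applied **zero-phase**
  (forward–backward); only the filter itself, not the application mode,
  was fixed upstream, and zero-phase application preserves R-peak timing,
  which the RR features depend on. The effective attenuation order doubles;
  the half-power points of the *designed* filter remain at 0.5/40 Hz and
  are measured from the transfer function by `filter_response()`.
  `signal::filtfilt` handles the very long transient of the 0.5 Hz edge
  poorly at signal boundaries, so the implementation demeans each lead and
  odd-reflect-pads 2 s on each side before filtering (the padding is
  trimmed afterwards).
* **Min–max normalization per lead per segment.** The normalization's
  scope (whole record vs segment) was open; per-segment scope is chosen so
  slow amplitude drift cannot leak information across windows. Flat
  (zero-range) segments map to zeros with a warning rather than erroring —
  they legitimately occur at synthetic-data edges.
* **Segmentation.** Δt = 10 s windows, 50% overlap, half-open 0-based
  windows `[start, start + N)`; a trailing partial window is dropped so the
  model input size is constant. Segment count is
  `floor((L − N)/stride) + 1`, property-tested against brute-force start
  enumeration.
* **Labels.** Alphabetical label codes (E = 0, N = 1, S = 2, V = 3).
  A window's label is the most severe class among the beats whose R sample
  falls inside it (V ≻ S ≻ E ≻ N) — a deliberate clinical-safety bias:
  a window containing even one ventricular beat is a ventricular window.
  A majority rule is available for sensitivity analyses.

## Features

R-peaks are detected once per segment per lead by a
derivative–square–moving-window-integrate detector with adaptive
signal/noise peak tracking, a 0.2 s refractory period, and localization to
the signal maximum within ±50 ms. All detector thresholds are relative to
the signal's own energy, so detection is amplitude-scale invariant. The
threshold coefficient (0.15 of the adaptive signal–noise range) was set
during design so that wide ventricular complexes — whose derivative energy
is roughly three-fold lower than normal beats — are retained; per-class
recall against the generator's ground truth is the regression test.

Each segment is split into T = 10 sub-windows (1 s at the 10 s default —
T was open and is sized so single beats are localized in time while each
sub-window still contains a beat at normal rates). Per sub-window and
lead, 14 features: mean RR, SDNN, mean HR, beat count (RR intervals are
attributed to the sub-window in which they *end*, so a premature interval
is visible locally); periodogram band powers over 0.5–4, 4–15 and
15–40 Hz with LF/HF ratio and dominant frequency; approximate entropy
(m = 2, r = 0.2·SD); Poincaré SD1/SD2; sub-window mean and SD. Missing
values (too few beats) are imputed to 0 with a parallel 0/1 observed mask,
keeping the model input fixed-size without sentinel values.

Numerical conventions worth noting:

* The periodogram is the one-sided `|FFT|²/(N·fs)` density, so
  `sum(power)·Δf` equals the mean square exactly (discrete Parseval) —
  the test suite asserts this at 1e-6 relative.
* Band powers use rectangle bin-sums over **half-open** bands `[lo, hi)`.
  Trapezoidal integration was considered and rejected: on discontinuous
  spectra it smears band edges by O(Δf) and double-counts the shared edge
  of adjacent bands, whereas half-open bin-sums tile the Parseval identity
  exactly.
* Approximate entropy is the standard Pincus estimator
  Φ^m(r) − Φ^{m+1}(r) with Chebyshev distance and self-matches included.
  A printed ratio-form variant of the definition circulating in the
  application literature leaves its distance terms undefined; the standard
  estimator is what "the commonly used approximate entropy" denotes, and
  the implementation is verified exactly against an independent O(N²)
  double-loop oracle.
* Poincaré SD1/SD2 are the population SDs of the lagged point cloud
  (RR_i, RR_{i+1}) rotated 45°; SD2 uses the cloud's own variance
  (Var(x) + Var(y) − SD1²) rather than 2·Var(rr) − SD1², which differ at
  finite n — the rotated-cloud form is exactly the geometric definition
  and is what the tests check against.

## Model

Input: segments × T × leads × 28. Per sub-window the GCN update
σ(Σ c_vu⁻¹ W h_u + b) runs over the lead graph (complete graph with
self-loops by default; c_vu = √(deg v · deg u)); a single shared W acts on
self and neighbours alike via the self-loop, the usual GCN convention.
After lead mean-pooling, sub-window vectors are linearly embedded,
positional encoding added, and an encoder-only transformer stack applied:
multi-head scaled dot-product attention, add & layer-norm (ε = 1e-5),
position-wise feed-forward with inner width 4·d_model, add & layer-norm,
inverted dropout in train mode. The classifier head is temporal mean-pool
→ ReLU FC → softmax. A decoder-style masked-attention path makes no sense
for whole-segment classification and is deliberately absent; extracted
features (not raw samples) are the model input, matching the
spatial-then-temporal fusion order (GNN per time step, transformer across
time).

Training is minibatch Adam on (optionally class-weighted) cross-entropy
with per-feature z-scoring fitted on the training split, early stopping on
validation loss (patience 5), and best-epoch checkpointing. The entire
forward/backward pass is hand-written vectorized R and was verified
against central finite differences on every parameter tensor. Weight
initialization is fan-scaled uniform from an explicit seed; argmax ties
break to the lowest class index.

Full-size defaults (learning rate 1e-4, batch 32, 3 GNN layers,
4 transformer layers, d_model 128, 8 heads, dropout 0.3, ReLU, Adam) are
the tuned reference configuration. The desk-scale experiments use
`small_model_config()`: d_model 32, one GNN and one transformer layer,
4 heads, **learning rate 1e-3**. The larger rate is a deliberate scaling
decision made up front: the compact model trains for roughly a thousand
optimizer steps, an order of magnitude fewer than the full-size setting
the 1e-4 rate was tuned for.

## Synthetic data: what it emulates and what it does not

Beats are sums of Gaussian deflections (P, Q, R, S, T) placed on an RR
grid — analytic morphology with exact peak/width control, which is what
makes peak-location and width tests exact. Class templates: S premature
(rr_scale 0.7) with reduced P; V moderately premature (0.85), absent P,
QRS widened 3×, inverted T; E on-time with the R center displaced +60 ms
and amplitude raised 1.5×. No morphology specification was inherited from
upstream; these defaults encode textbook class differences and are fully
overridable. Noise: deterministic-phase baseline (0.1 mV at 0.3 Hz) and
powerline (0.02 mV at 50 Hz) sinusoids plus seeded white noise
(0.02 mV); leads are gain-scaled copies with independent noise.

Per-beat class probabilities default to N 0.89, S/V/E ≈ 0.037 each: with
~12 beats per 10 s window and severity labelling this yields roughly
class-balanced *segment* labels (the chance a window stays N is ~25%).

The generator deliberately does **not** model: dipole-based lead
geometry, respiration coupling, atrial-fibrillation RR dynamics, motion
artifacts, electrode drop-out, or inter-patient morphology variability
beyond the seeded jitter. Passing the synthetic benchmark therefore shows
that the pipeline's machinery is correct and that the model can learn
class-discriminative spatio-temporal structure — it does not certify
performance on clinical recordings, where class overlap and noise are far
harsher.

## Reference experiments and problem sizes

* End-to-end benchmark: 12 synthetic patients × 850 s at 125 Hz
  (~2000 labelled 10 s segments), strict patient-level hold-out (25% of
  patients), compact model, ≤ 15 epochs. Run by the acceptance test and
  `scripts/acceptance.R`; held-out accuracy and macro-F1 are the reported
  quantities.
* Ablation direction: 8 patients × 420 s, three seeds, 15 epochs,
  variants hybrid / GNN-only (transformer replaced by temporal mean-pool)
  / transformer-only (identity lead graph). The comparison is on the mean
  over seeds. With only two highly correlated synthetic leads the spatial
  branch carries limited extra information, so the expected result is
  parity, not dominance.
* Grid search and t-test machinery are exercised at toy scale (the
  divergent-learning-rate candidate must lose; the closed-form hand case
  must match to 1e-9).

## Known limitations

* Two synthetic leads differing by gain and noise make the lead graph
  nearly degenerate; correlation-strategy graphs on real multi-lead data
  are the intended use of the GNN branch.
* The compact model's accuracy on minority classes depends on the
  detector finding premature beats near segment boundaries; RR intervals
  spanning a segment edge are lost by design (segments are processed
  independently).
* `optimize_thresholds()` tunes each class independently with the others
  at zero; jointly optimal threshold vectors are out of scope.
* WFDB support is a deliberate subset: single-segment records, format 16,
  one `.dat` per record; annotations travel as CSV.
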