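---
title: "Methods: multimodal emotion-intensity recognition from flight biosignals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal emotion-intensity recognition from flight biosignals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(affectflight)
```

## Overview

`affectflight` estimates the intensities of five emotions — happy, sad,
angry, surprised, scared, each in [0, 1] — from three physiological
modalities recorded during simulated flights: heart rate (HR), galvanic
skin response (GSR) and eight-channel EEG. Face-reading software provides
the training targets; once trained, the network predicts intensities from
the biosignals alone. The pipeline is: preprocessing → windowing →
feature extraction → SVD feature selection → MLP regression →
realtime output correction (RTOR) → leave-one-flight-out evaluation.

Because no recordings of this design are publicly deposited, the package
includes a first-class synthetic cohort generator; every stage is tested
against it, and all evaluation figures in the README come from it.

## The synthetic cohort: what it emulates

A session is a seven-task flight (takeoff, climbing, cruise, descent,
approach, final approach, landing). Defaults in `synth_config()` define
the simulated study conditions:

* **13 flights**, 600 s each. Sampling rates mirror device classes used
  for this kind of acquisition: HR 1 Hz (pulse-trend logger), GSR 16 Hz
  (the Shimmer-class DC–15.9 Hz analog band), EEG 500 Hz (Enobio-class),
  face video 30 Hz. The original logging rates are not published, so these
  are package choices, configurable per modality.
* **Latent emotion process.** Each emotion follows a discretized
  Ornstein–Uhlenbeck process reverting (θ = 0.5 s⁻¹, σ = 0.06) to a
  per-task mean, clipped to [0, 1]. The 5 × 7 mean matrix gives every task
  one clearly dominant emotion, and task durations are set so each emotion
  dominates ≈ 20 % of the session. That balance is deliberate: it puts the
  chance level of the major-emotion match statistic at 1/5, so a model
  with no physiological information scores ≈ 0.2 regardless of which
  emotion it prefers.
* **Coupling.** Arousal = scared + surprised. HR is a 72 bpm baseline plus
  slow wander plus beat-to-beat jitter with sd = 0.4 + 6·arousal bpm (so
  the Poincaré dispersion of the RR series tracks arousal). GSR is a slow
  tonic drift plus exponential-decay phasic events (τ = 2 s) firing at
  0.04 + 0.5·arousal events/s. Each EEG channel is broadband Gaussian
  noise (sd 3 µV) plus a 12–30 Hz band-limited component with power
  2 + 12·(wᵀ·latent) µV², where the fixed 8 × 5 loading matrix w is full
  rank — the five intensities are identifiable from the eight band powers.
* **Observed face trace** = latent + truncated Gaussian noise (sd 0.02),
  clipped to [0, 1]; window-mean face intensities are the regression
  targets.

What the generator does **not** emulate: real ECG morphology or EEG
dipole physics, motion artifacts, electrode drift, inter-subject
variability, or the label noise of a face-reading engine (its
misclassifications are a major error source on real data). Passing the
recovery tests therefore shows the pipeline is statistically sound and
leak-free — not that it would reach the same numbers on real recordings.

Reproducibility: one master seed; per-session seeds come from a stable
polynomial hash of the session id, so cohorts are identical across
platforms and sessions are uncorrelated by construction.

## Preprocessing

Stage order (each stage preserves sample count): linear detrend →
abrupt-change correction → min-max normalization → (EEG only) zero-phase
band-pass → windowing.

* **Abrupt-change correction** replaces samples whose robust z-score
  against a rolling median/MAD (window 1 s, threshold 5) exceeds the
  threshold. Two numerical guards matter: samples within half a window of
  the ends are kept as-is, and the rolling MAD is floored at a tenth of
  the series' global MAD. Without the floor a noiseless smooth signal has
  locally zero MAD, the z-score is unbounded, and the filter "corrects"
  curvature; with it, the correction is idempotent and leaves clean
  signals untouched.
* **Normalization** is min-max to [0, 1] per session; a constant series
  maps to 0.5 by convention.
* **Beta band-pass**: 4th-order Butterworth, 12–30 Hz, applied
  forward–backward (`signal::filtfilt`) for zero phase; requires
  fs > 60 Hz.
* **Windowing**: 10 s windows, no overlap by default. Window length is the
  single most consequential free parameter (it sets the sample count per
  flight and the HR window length); it is a config knob. Windows keep each
  modality at its native rate — features are rate-aware, so no resampling
  is invented.

One deliberate split: the Poincaré block is computed from the
abrupt-corrected HR window still in **bpm** (`hr_clean`), because
RR = 60000/HR is undefined at the normalized minimum. The statistical HR
features use the fully processed window.

## Features (90 per window)

| block | count | features |
|---|---|---|
| HR | 11 | MN, MD, STD, VAR, ENT, RNG, RMS, SD1, SD2, SCT, SAR |
| GSR | 7 | MN, MD, STD, VAR, ENT, RNG, PEK |
| EEG ×8 | 9 each | MN, MD, STD, VAR, ENT, RNG, RMS, WAC, WDC |

* STD/VAR are population moments (divisor n), and VAR ≡ STD².
* **ENT** is a histogram plug-in estimate of differential entropy in nats
  with Freedman–Diaconis bin widths; constant windows return a −20 nat
  floor. The log base is a package choice (natural log).
* **RNG** defaults to max − min; an endpoints mode (|last − first|) is
  available — the two definitions both appear in the field.
* **PEK** counts local maxima with topographic prominence ≥ 0.05
  (normalized units) per second — the phasic-event rate.
* **WAC/WDC** are the means of the level-4 sym7 approximation and detail
  coefficients of a multilevel DWT (at 500 Hz the level-4 detail band is
  ≈ 16–31 Hz, i.e. the beta rhythm). The transform is implemented in the
  package (symmetric extension, Mallat pyramid) because no R wavelet
  package is available in the target environment; its coefficients are
  tested to 1e-8 against values frozen from an independent
  implementation. The continuous transform is the textbook starting
  point, but EEG windows are discrete, so the discrete transform is the
  realization.
* **SD1/SD2/SCT/SAR**: with x = RR₁..RRₙ₋₁, y = RR₂..RRₙ and centroid
  (x̄, ȳ): d1ᵢ = |(xᵢ−x̄)−(yᵢ−ȳ)|/√2, d2ᵢ = |(xᵢ−x̄)+(yᵢ−ȳ)|/√2,
  SD1 = √(mean d1²), SD2 = √(mean d2²) (mean, not n−1, exactly as the
  defining equations are printed), SCT = √(x̄²+ȳ²), SAR = π·SD1·SD2.

The GSR block is seven features: the stated per-modality count governs
the pipeline, and RMS is the dropped eighth candidate (configurable).

## SVD feature selection

Whether the original analysis projected onto singular directions or
selected original columns is ambiguous; both are provided, and column
selection is the default because per-modality retained counts (6 HR,
4 GSR, 5 per EEG channel = 50) only make sense for identity-preserving
selection. Per block, the column-centered matrix is decomposed A = U D Vᵀ
and column j scored by √Σₖ(dₖ v_jk)² over the leading k directions
(k = the block's retained count); ties break to the lower column index.
Selection is unsupervised, row-order invariant, and reduces to the
identity when the counts equal the block widths. SVD is computed per
modality block, not on the 90-wide matrix, because the retained counts
are stated per modality.

## The network

A from-scratch MLP (no framework): induced local field
v_j = Σᵢ w_ji xᵢ + b_j; hidden activation sigmoid (slope a ≥ 1, default 1)
or ReLU; output layer sigmoid for regression (five independent
intensities in (0,1)) or softmax for classification. Training minimizes
the mean error energy ξ = ½(d−y)² summed over output neurons:

* output delta δ = ε·y(1−y) (the sigmoid derivative; the ReLU subgradient
  1{v>0} replaces it in ReLU mode, with the subgradient at 0 set to 0);
* hidden deltas by the standard chain rule;
* the delta-rule update Δw(n) = α·Δw(n−1) + η·δ·y_pre uses the
  **presynaptic** activation — the textbook form — where the printed
  equation's subscript reads as the postsynaptic output; the divergence
  is deliberate and documented here;
* `adam` applies Adam (β₁ 0.9, β₂ 0.999, ε 1e-8) to the same gradients.

Training is full-batch: the defining equations fix the per-sample
quantities but not an update schedule, and one update per epoch on the
mean gradient makes the 13-fold cross-validation run in seconds per fold
at desk scale. Initialization is Glorot-uniform from a seed; biases start
at zero; gradients are verified against central finite differences to
1e-5 for both activations and both output heads.

Inputs are column-centered (the test matrix's CC toggle, fit on the
training folds only) and then always scaled by the training-fold column
sd. The scaling is a package addition: the 90 features span several
orders of magnitude of units (ms² ellipse areas next to normalized
intensities), and a sigmoid MLP cannot train across that spread.

`network_spec()` defaults to 6000 epochs (the published training length);
`loocv()` overrides to 500 epochs and a 83 × 2 hidden layout (the
feature-mode architecture) so the full cross-validation finishes in
about half a minute — the reduced-epoch evaluation regime.

## RTOR — realtime outliers removal

The five output channels are corrected causally and independently: a
sample deviating from the median of the last N = 20 **raw** outputs by
more than k·max(MAD, 0.1) with k = 4 is replaced by that median; the
first N samples are warm-up. Two choices matter and were measured:

* The batch holds the raw history, not the corrected history. A
  corrected-history batch locks onto the pre-transition level after a
  genuine task change and flattens the rest of the segment — on the
  synthetic cohort this cut match accuracy from ≈ 0.96 (no RTOR) to
  ≈ 0.45, while the raw-history batch re-adapts within half a batch.
* The MAD floor (0.1, in intensity units, sized for [0,1] outputs) keeps
  the filter aimed at genuinely abrupt glitches: in a flat stretch the
  MAD collapses and, unfloored, any legitimate movement would be flagged.

The filter is idempotent for isolated spikes, never moves a corrected
value outside the batch range, and passes clean samples through
bit-identically.

## Evaluation

Per emotion: RMSE = √(Σ(ŷ−y)²/N) and MAE = Σ|y−ŷ|/N over the held-out
flight's windows (MAE ≤ RMSE always). The major-emotion match accuracy is
the fraction of windows where argmax(prediction) = argmax(target), ties
broken by the fixed emotion order (happy, sad, angry, surprised, scared)
on both sides.

Leave-one-flight-out cross-validation holds out each session exactly
once; feature selection, centering and scaling are re-fit on the training
folds only, and the fold partition is asserted leak-free by session id.
Sessions too short to yield a single window are skipped with a warning.
`run_test()` exposes the 34-row test matrix (raw-data vs featured,
SVD on/off, sigmoid/ReLU × sgd/adam, modality masks); raw-data mode feeds
the concatenated normalized raw window samples directly to the network,
with the resulting input width recorded in the report.

## Problem sizes and observed behaviour

The shipped evaluation uses the default conditions: 13 × 600 s sessions,
10 s windows (60 per flight, 780 in all), 50 selected features, 83 × 2
hidden units, 500 epochs. Under these conditions the feature-selected
sigmoid/adam test reaches a cohort-mean match accuracy of ≈ 0.6 with
per-emotion RMSE ≤ ≈ 0.19 (see the README for one seed's full table),
and a zero-coupling control cohort sits at the 0.2 chance level. These
numbers are recomputed by `scripts/acceptance.R` and asserted (with the
frozen thresholds: accuracy > 0.5, per-emotion RMSE < 0.25, control
within 0.08 of chance) in the test suite.

## Known limitations

* Statistical emulation only: no biophysical signal models, no artifact
  processes, no subject effects — synthetic results bound what the code
  does, not what real recordings would yield.
* The published per-flight error tables were computed on undeposited
  recordings and are not reproduction targets here.
* Raw-data mode feeds very wide inputs (tens of thousands of samples per
  window at 500 Hz EEG); it exists for completeness of the test matrix
  and is practical only at reduced sampling rates or window lengths.
* The RTOR batch length/threshold trade-off is stream-length dependent:
  with ~60 windows per flight and ~7 genuine level changes, aggressive
  settings degrade rather than clean the trace (measured above).
* Differential entropy on 10-sample HR windows is a coarse plug-in
  estimate; it is retained because the feature set fixes the block
  composition, not because it is individually reliable at that n.
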