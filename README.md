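# affectflight

Multimodal emotion-intensity recognition from simulated-flight biosignals.

## The problem

During a simulated flight a pilot's affective state changes with the flight
phase — takeoff, climbing, cruise, descent, approach, final approach,
landing. Commercial face-reading software can score the intensities of five
emotions (*happy, sad, angry, surprised, scared*, each in [0, 1]) from video,
but a wearable-only system must infer those intensities from physiological
signals alone: heart rate (HR, bpm), galvanic skin response (GSR, µS) and
eight-channel EEG (µV, 10–20 montage Fp1, F3, C3, T7, Fp2, F4, C4, T8,
beta band 12–30 Hz).

`affectflight` implements that pipeline end to end for R users working in
psychophysiology and affective computing:

1. **Synthetic cohort generator** — no public recordings exist for this
   design, so the package ships a generator that emulates the study
   conditions: 13 flight sessions, a seven-task schedule, a latent
   Ornstein–Uhlenbeck 5-emotion process with per-task means, and modalities
   coupled to it (beat-to-beat HR dispersion and electrodermal phasic-peak
   rate grow with arousal; per-channel EEG beta power is an affine function
   of the latent intensities).
2. **Preprocessing** — linear detrend, robust abrupt-change correction
   (rolling median/MAD), min-max normalization, zero-phase 4th-order
   Butterworth beta band-pass for EEG, and windowing into synchronized
   10 s samples whose regression target is the window-mean face intensity.
3. **Features** — 90 per window: 11 HR (summary statistics, differential
   entropy, range, RMS, and the Poincaré descriptors SD1, SD2, centroid
   norm ‖C‖ and ellipse area SA = π·SD1·SD2 of the RR series), 7 GSR
   (statistics plus phasic peak rate), and 9 × 8 EEG (statistics plus sym7
   wavelet approximation/detail coefficient means).
4. **SVD feature selection** — per modality block A = U D Vᵀ on the
   column-centered block; columns ranked by singular-value-weighted loading
   norms; 6 HR + 4 GSR + 5-per-EEG-channel = 50 features kept.
5. **MLP regressor, written from its equations** — induced local field
   v_j = Σ w_ji x_i + b_j, sigmoid φ(v) = 1/(1+e^{-av}) or ReLU hidden
   units, sigmoid outputs for the five intensities (softmax available for
   classification), error energy ξ = ½(d−y)², output delta
   δ = ε·y(1−y), delta-rule updates with momentum
   Δw(n) = αΔw(n−1) + η·δ·y_pre, or Adam on the same gradients.
6. **RTOR** (Realtime Outliers Removal) — causal correction of abrupt
   network outputs against the median/MAD of the last N raw outputs.
7. **Evaluation** — leave-one-flight-out cross-validation with per-emotion
   RMSE and MAE and the major-emotion match accuracy (fraction of windows
   whose predicted argmax emotion equals the target argmax), plus the
   34-row test matrix toggling preprocessing, feature extraction, SVD,
   activation, optimizer and modality masks.

## Worked example

```r
library(affectflight)

cfg    <- synth_config(rng_seed = 1)     # 13 flights, 600 s, HR 1 Hz / GSR 16 Hz / EEG 500 Hz
cohort <- generate_cohort(cfg)
report <- run_test(21, cohort, seed = 1) # detrend+outliers+FE+SVD+CC, sigmoid, adam
report
```

```
<eval_report> 13 folds, input width 50
per-emotion cohort means:
    emotion rmse_mean rmse_sd mae_mean  mae_sd
1     happy    0.0656  0.0144   0.0457 0.00884
2       sad    0.1689  0.0244   0.0879 0.01881
3     angry    0.1503  0.0223   0.0803 0.01295
4 surprised    0.1557  0.0165   0.0771 0.00681
5    scared    0.1116  0.0546   0.0591 0.02245
match accuracy: 0.632 +/- 0.056
```

Each row is the cohort mean ± sd over the 13 held-out flights of the
per-emotion error between the predicted and target intensity traces; the
match accuracy is the share of windows whose dominant predicted emotion is
the dominant target emotion (chance level 1/5). The input width 50 confirms
the 6 + 4 + 40 SVD-selected feature structure; `run_test(5, ...)` runs the
all-features variant (width 90).

Lower-level entry points: `preprocess_session()`, `windowize()`,
`build_feature_matrix()`, `select_features()`, `network_spec()` /
`train_network()` / `predict_emotions()`, `rtor_filter()`, `loocv()`,
and `write_cohort()` / `read_cohort()` for the per-modality CSV format.

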