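Package: affectflight
Title: Multimodal Emotion-Intensity Recognition from Simulated Flight Biosignals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for recognizing the intensities of five facial
    emotions (happy, sad, angry, surprised, scared) from synchronized
    physiological recordings -- heart rate, galvanic skin response and
    eight-channel EEG -- collected during simulated flights. Provides a
    synthetic flight-session generator with task-driven latent emotion
    dynamics, signal preprocessing (detrending, robust outlier correction,
    min-max normalization, zero-phase beta-band filtering, windowing), a
    90-column feature set (Poincare heart-rate-variability descriptors,
    differential entropy, symlet wavelet coefficients, electrodermal peak
    rates and summary statistics), SVD-based feature selection, a multilayer
    perceptron regressor trained by delta-rule backpropagation with momentum
    or Adam, realtime outlier removal on the network outputs, and a
    leave-one-flight-out evaluation harness reporting per-emotion RMSE, MAE
    and major-emotion match accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
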