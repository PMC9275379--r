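Package: microfusion
Title: Multimodal Emotion Recognition from Facial Micro-Expressions, EEG,
    and Peripheral Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for binary arousal/valence recognition from synchronized
    facial video, EEG, galvanic skin response (GSR) and photoplethysmography
    (PPG) recordings. A micro-expression spotting step locates the apex frame
    of each trial from regional pixel differences, a window of frames and a
    matched window of signal samples around the apex are extracted as regions
    of interest, per-modality classifiers (a 3D convolutional video model, a
    stacked LSTM over band-power and statistical feature sequences, and
    cost-sensitive SVM/KNN/random-forest baselines) are trained under a
    leave-some-subject-out protocol, and the per-modality decisions are fused
    by majority vote or a weighted probability sum whose weights are searched
    on the training folds. A reproducible synthetic multimodal generator with
    known ground truth (latent affect states, planted apex frames, effect
    sizes) supports development and end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
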