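Package: emgSBL
Title: Movement-Intention Recognition from Multichannel Surface EMG with a
    Sine-Chaotic Black Widow Optimized LSSVM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for decoding limb movement intention from multichannel
    surface electromyography (sEMG). Provides a synthetic 16-channel sEMG
    generator with ground-truth labels, standard preprocessing (bias removal,
    zero-phase band-pass and notch filtering, peak normalization, sliding
    windows), six classical per-channel features (MAV, RMS, VAR, iEMG, mean
    frequency, median power frequency), multi-class Fisher-dispersion feature
    scoring with genetic-algorithm subset selection, a closed-form least
    squares support vector machine (LSSVM) with RBF kernel assembled
    one-vs-one for multiclass, and a black widow optimization metaheuristic
    with sine chaotic initialization that tunes the LSSVM hyperparameters by
    cross-validation. Includes end-to-end discrete-trial evaluation and
    continuous-stream decoding with confusion matrices, per-class accuracy
    and macro one-vs-rest ROC/AUC.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    e1071,
    nnet,
    class,
    randomForest,
    rpart,
    arrow
Config/testthat/edition: 3
RoxygenNote: 7.3.3
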