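Package: pcgst
Title: Stockwell-Transform Deep-Feature Screening of Phonocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for murmur identification and clinical
    outcome screening from phonocardiogram (PCG) recordings. Computes
    discrete Stockwell transforms of heart-sound signals over a selected
    frequency band, converts the amplitude time-frequency maps to images,
    extracts deep features with an AlexNet-shaped convolutional backbone,
    fuses features across the four auscultation locations per patient,
    reduces dimensionality by recursive feature elimination (linear-SVM
    ranking) or principal component analysis, rebalances training data with
    SMOTE, classifies with linear SVM, random forest or gradient boosting,
    and scores with the CinC/PhysioNet 2022 clinical metrics (weighted
    accuracy and the outcome cost function). Includes a synthetic PCG cohort
    simulator (S1/S2 heart sounds plus band-limited systolic murmur noise)
    so the whole pipeline is testable without access to clinical data.
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
    ranger,
    xgboost,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
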