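Package: neurofuse
Title: Hybrid Multimodal Fusion Classification of Autism Spectrum
    Disorder from Eye Fixation, Facial Expression, and EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feature extraction and two-level hybrid fusion
    classification for distinguishing children with autism spectrum
    disorder (ASD) from typically developing (TD) children using three
    data modalities: eye-fixation coordinates (area-of-interest
    distribution frequencies via K-means clustering), per-frame facial
    expression labels (target-expression counts in consecutive
    40-frame windows), and 14-channel EEG (five-band spectral power by
    brain region, screened by independent-samples t-tests). Behavioral
    features are fused at the feature level, physiological features
    are classified independently, and the resulting subdecisions are
    fused by an attribute-weighted naive Bayes classifier. Includes a
    synthetic multimodal cohort generator with plantable group
    effects, a leakage-safe leave-one-out cross-validation harness,
    and column-normalized confusion-matrix reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    randomForest,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
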