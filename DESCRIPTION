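Package: eegfd
Title: EEG Complexity Analysis with Higuchi Fractal Dimension and Fuzzy
    Partition Memberships
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multichannel resting-state EEG complexity
    for staging opium addiction: deterministic preprocessing (FIR band-pass,
    50 Hz notch, common average reference, bad-channel interpolation,
    amplitude-based segment rejection), Higuchi Fractal Dimension feature
    extraction with feature-to-channel attribution, fuzzy partition-membership
    feature transformation via a decision-tree partition generator, attribute
    ranking (correlation, chi-squared, PCA loading priority, probabilistic
    significance), multi-scheme cross-validated MLP/SVM classification with a
    full per-class metric panel (TP/FP rate, precision, recall, F, MCC,
    ROC/PRC areas), and channel-wise group statistics (Lilliefors normality,
    one-way ANOVA, Tukey HSD). Includes a synthetic cohort generator based on
    fractional Gaussian noise with analytically known fractal dimension, so
    the whole pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    rpart,
    nnet,
    e1071,
    nortest,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
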