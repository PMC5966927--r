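Package: cxrtriage
Title: Hybrid Normal/Abnormal/Uncertain Triage of Chest Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-level triage of grayscale chest radiographs from two
    complementary scores: the reconstruction error of a convolutional sparse
    denoising autoencoder trained on normal studies, and the abnormality
    probability of a classifier head fitted on fixed image features. The two
    scores are combined by maximizing the empirical (Mann-Whitney) area under
    the ROC curve over linear coefficients and over a reconstruction-error /
    probability threshold pair, and a multi-classifier vote assigns each study
    to the normal, abnormal or uncertain level. Includes a seeded phantom
    radiograph generator, deterministic preprocessing (histogram equalization,
    lung-box cropping, bilinear down-sampling, rotation/shift augmentation),
    feature-space rebalancing (SMOTE with Tomek-link and edited
    nearest-neighbour cleaning), focal-loss training, and evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
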