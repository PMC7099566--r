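Package: dotcad
Title: Computer-Aided Diagnosis of Breast Lesions in Diffuse Optical Tomography Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for classifying benign versus malignant
    breast lesions in diffuse optical tomography (DOT) absorption volumes with a
    small convolutional neural network implemented from scratch (convolution,
    batch normalization, sigmoid activations, average pooling, softmax
    classifier, and full backpropagation, with no neural-network framework).
    Includes a synthetic DOT phantom generator that emulates a clinical cohort
    of 91 x 91 x 31 voxel absorption volumes, axial slicing and normalization to
    32 x 32 network inputs, stratified splitting with minority-class flip
    augmentation, mini-batch SGD-with-momentum training with early stopping on a
    monitored misclassification rate, and an evaluation suite with confusion
    metrics, ROC/AUC, learning-rate sweeps, and stratified k-fold
    cross-validation. Volumes are stored as NIfTI-1 files with CSV manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
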