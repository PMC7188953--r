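Package: radiotexnet
Title: CT Radiomic Texture Features and Neural-Network Classification of
    Lung Tumor Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-dimensional CT radiomics pipeline for discriminating two
    lung-cancer classes from segmented tumor regions of interest. Computes
    histogram-based global features and four families of texture features
    (gray-level co-occurrence, run-length, size-zone and neighborhood
    gray-tone difference matrices) at multiple Lloyd-Max gray-level
    quantizations, expands the feature set over the eight subbands of a
    single-level 3D discrete wavelet transform, selects features by
    correlation pruning and minimal-redundancy-maximal-relevance mutual
    information filtering, and classifies with a small tanh multilayer
    perceptron trained by the Levenberg-Marquardt algorithm, evaluated by
    repeated random train/validation/test splits with averaged ROC curves.
    Includes a synthetic two-class tumor-phantom cohort generator and an
    independent brute-force texture oracle so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    RNifti,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
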