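Package: marrowtex
Title: SVM Texture Classification of Diffuse Bone-Marrow Infiltration on
    Lumbar-Spine MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of an SVM texture-classification
    pipeline that discriminates diffuse hematologic marrow infiltration from
    normal marrow on sagittal T1-weighted lumbar-spine MRI. Provides a seeded
    synthetic spine-phantom generator (correlated marrow textures, disk
    compartments, vendor intensity heterogeneity, focal confounds),
    annulus-fibrosus disk normalization, 3D GrowCut cellular-automaton
    segmentation, population-minimal raw-pixel window featurization, SVM
    kernel/grid-search experiments with 5-fold cross-validation,
    diagnostic-accuracy statistics (Wilson intervals, DeLong AUC comparison,
    McNemar, Cohen's kappa), and inverse-power-law learning-curve fitting for
    sample-size estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    minpack.lm,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
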