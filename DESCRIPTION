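Package: radct
Title: Radiomics Texture Maps and CNN-ViT Ensemble Classification for Volumetric CT
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying volumetric chest CT scans without
    region-of-interest annotation. The package computes per-voxel 3D Haralick
    gray-level co-occurrence texture maps, selects the most discriminative map
    by random-forest Gini importance over patch statistics, and classifies
    volumes with a multichannel ensemble of a 3D convolutional network and a
    3D vision transformer fused before a sigmoid head. It includes HiResCAM
    and attention-rollout visual explanations, a stratified k-fold
    cross-validation and ablation harness with the standard diagnostic metric
    suite, a synthetic 3D texture-phantom generator for fully reproducible
    desk-scale experiments, and NIfTI / DICOM-series input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    RNifti,
    randomForest,
    pROC,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
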