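Package: tumorburden
Title: Whole-Brain Tumor Burden Detection Analysis for Multimodal PET and MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline quantifying how well in vivo imaging (gadolinium
    enhanced T1-weighted MRI, T2-weighted MRI, amino acid PET, and their
    combinations) detects whole-brain tumor burden against an ex vivo
    fluorescence ground truth. Provides axis-aligned volume geometry with
    NIfTI input/output, nearest-neighbour and block-mean resampling across
    anisotropic grids, landmark-based least-squares affine registration
    (3D and slice-by-slice 2D), threshold segmentation with exclusion
    regions and metric (millimetre) mask expansion, voxel-wise detection
    scores (sensitivity, specificity, Dice, worst-case surface distance),
    exact nonparametric group comparisons (zeros-discarded signed-rank and
    rank-sum tests by full enumeration), a contralaterally normalized PET
    correlate regression with partial-regression plots, and a synthetic
    multimodal phantom generator used as the pipeline's test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
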