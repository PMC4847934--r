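Package: reactivatr
Title: Cross-Decoding Analysis of Awake Offline Memory Reactivation in
    Block-Design fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates block-design BOLD fMRI sessions for a paired-associates
    learning paradigm with distractor and immediate-recall conditions, and
    analyses them with a mass-univariate GLM functional localizer (Gaussian
    smoothing, voxelwise familywise-error thresholding, sphere regions of
    interest), a block-cross-validated linear support vector machine
    multi-voxel pattern analysis scored as d-prime, a cross-decoding test for
    reactivation of encoding-period patterns during a distractor task, a
    temporal-proximity control correlation, and nonparametric group inference
    (exact and approximate one-tailed Wilcoxon signed-rank tests, paired
    t-tests). A plantable multivariate reactivation signal of configurable
    strength makes every stage testable end to end without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
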