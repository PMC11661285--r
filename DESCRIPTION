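Package: braingap
Title: Brain-Based BMI-Gap Modelling from Voxel-Wise Grey Matter Volume
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to learn a brain-based body-mass-index (BMI) predictor from
    voxel-wise grey matter volume under repeated nested cross-validation,
    derive bias-corrected BMI-gap scores (predicted minus measured BMI),
    visualize predictive voxel patterns with cross-validation-ratio and
    sign-based consistency maps, relate shared BMI/disease voxel patterns to
    clinical variables via sparse partial least squares, and evaluate the BMI
    gap as a predictor of future weight gain.  A phantom-cohort simulator with
    known ground truth makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
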