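Package: femstrength
Title: QCT-Based Finite Element Estimation of Femoral Strength
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates proximal femoral strength from quantitative computed
    tomography (QCT) by phantom-based density calibration, piecewise
    density-to-modulus and density-to-yield material laws, voxel hexahedral
    meshing with PMMA loading pads, and a small-strain elastic-perfectly-plastic
    finite element compression solve reporting the reaction force at 4%
    compressive deformation. Includes generators for synthetic CT volumes with
    known ground truth and synthetic subject cohorts, plus the small-sample
    nonparametric statistics (exact Mann-Whitney U, Spearman correlation) and
    hierarchical multiple-linear-regression model ladder used to identify
    predictors of femoral strength in diabetic and control cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    MASS,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
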