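Package: torsotopo
Title: Automated Surface-Topographic Measurement of Trunk Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated surface-topography pipeline for spinal deformity
    assessment. Registers a symmetric torso template atlas to a raw 3D torso
    scan with stiffness-regularized nonrigid ICP, derives nine anatomical
    landmarks, and computes a suite of intrinsic (spine length, back surface
    area, cross-sectional areas and volumes) and pose-dependent (back surface
    rotation, centroid deviation, trunk axial rotation, Qangle) trunk-shape
    measurements. Includes a parametric generator of watertight scoliotic
    torsos with analytic ground truth, and reliability statistics (ICC(2,1)
    with 95% confidence intervals, RMS error, Spearman consistency screens
    with Bonferroni-Holm correction) for test-retest, remove-replace and
    inter-rater study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
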