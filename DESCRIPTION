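Package: faceval
Title: Validation Toolkit for 3D Facial Surface Models
Version: 0.1.0
Authors@R: person("faceval", "developers", role = c("aut", "cre"),
    email = "faceval@example.org")
Description: Accuracy-validation pipeline for 3D facial soft-tissue models
    against a reference optical face scan: Wavefront OBJ / landmark JSON
    input-output, a synthetic face-pair generator with analytically known
    deviations, two-step rigid registration (landmark-based Kabsch alignment
    followed by point-to-surface iterative closest point refinement),
    anatomical-frame construction from the bilateral tragions and the soft
    tissue Frankfort horizontal plane, signed point-to-surface deviation
    fields with region-wise root mean square error and color-coded map
    export, per-axis landmark deviation decomposition, the twelve standard
    linear and angular soft-tissue anthropometric measurements, 2D photo
    repositioning geometry, and method-error statistics (paired t test,
    two-way absolute-agreement average-measures intraclass correlation,
    Bland-Altman limits of agreement, and exact noncentral-t paired-design
    sample size).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
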