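Package: cinestrain
Title: Myocardial Strain Quantification from Short-Axis Cine-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated workflow for global and regional myocardial strain
    analysis from short-axis cine-MRI. Small convolutional encoder-decoder
    networks perform ventricular centering, four-class cardiac segmentation
    (background, right ventricle, left-ventricular myocardium, cavity) and
    unsupervised deformable motion estimation with an anatomically
    constrained, diffusion-regularized loss; a deterministic engine converts
    the estimated displacement fields into Green-Lagrange strain in
    cylindrical coordinates, global and AHA-segment strain and strain-rate
    curves, and scalar indices (end-systolic strain, peak systolic and
    early-diastolic strain rate). Includes an analytic contracting and
    twisting left-ventricle phantom with closed-form ground-truth motion and
    strain, plus the evaluation statistics used for segmentation, motion and
    test-retest repeatability studies (Dice, Hausdorff distance, volumetrics,
    landmark end-point error, Bland-Altman, intraclass correlation, relative
    change).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
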