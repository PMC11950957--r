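Package: rtdosepred
Title: Anatomy-Driven Dose Prediction and Rectal NTCP Estimation for
    Prostate Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for estimating late-rectal-toxicity risk
    from patient anatomy in prostate volumetric modulated arc therapy
    (VMAT). Generates synthetic pelvic phantoms with PTV-conformal,
    rectum-sparing dose distributions; trains a compact 2D U-net
    (implemented in C++ via Rcpp/RcppArmadillo) to predict 3D dose from
    CT-like images and organ masks; and evaluates predictions with
    dose-volume histogram (DVH) metrics, isodose Dice similarity, and
    normal tissue complication probability (NTCP) under the
    Lyman-Kutcher-Burman and relative-seriality models with EQD2
    conversion. Includes cohort-level statistical reporting (coefficient
    of determination, Wald tests, power analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
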