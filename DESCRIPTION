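Package: nsbm
Title: Sensitivity-Calibrated Noisy-Student Detection of Small Brain
    Metastases in 3D MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end framework for detecting small (<15 mm) brain
    metastases in contrast-enhanced 3D T1-weighted MRI volumes.  Lesion
    candidates are generated with a constrained multi-scale
    Laplacian-of-Gaussian blob detector, classified by a family of 3D
    convolutional patch classifiers (CropNet), and improved with a
    sensitivity-calibrated noisy-student semi-supervised training loop
    that pseudo-labels a large unlabeled cohort at a response threshold
    calibrated to a target detection sensitivity.  Performance is
    summarised with FROC curves (lesion sensitivity versus average false
    positives per exam, 1.5 mm matching tolerance).  Because clinical
    cohorts of this kind are private, the package ships a synthetic
    phantom generator that emulates the labeled/unlabeled cohort
    structure and lesion statistics, so the whole pipeline is exercisable
    on any machine.
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
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    knitr
Config/testthat/edition: 3
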