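Package: aortaq
Title: Automated Thoracic Aorta Quantification from CT-Like Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end quantification of the thoracic aorta in 3D CT-like
    volumes: aortic segmentation (a compact 3D U-Net trained with Adam on
    cross-entropy, plus a deterministic intensity-prior segmenter),
    multi-scale reinforcement-learning detection of five aortic landmarks,
    medialness-weighted centerline extraction with rotation-minimizing
    cross-sectional frames, partition into ascending/arch/descending
    sections, maximal average diameter measurement perpendicular to the
    centerline, and aortic dissection screening by straightening the vessel
    along its centerline and pooling per-slice RBF-SVM probabilities.
    Includes a seeded synthetic "candy-cane" aorta phantom generator with
    analytic ground truth (centerline, radius profile, landmarks, dissection
    labels) and a method-agreement statistics toolbox (ICC(2,1),
    Bland-Altman limits of agreement, exact Wilcoxon signed-rank, Spearman
    correlation, Clopper-Pearson confidence intervals for diagnostic
    metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    igraph,
    e1071,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
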