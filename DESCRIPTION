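Package: gliohbm
Title: Two-Level Histogram-Based Morphometry and Expanding Segmentation for Glioma MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided analysis of T2-FLAIR brain MRI for glioma
    detection and grading. Implements z-score intensity standardization with
    clipping, a two-level classification framework (per-cell histogram of
    oriented gradients, fuzzy c-means encoding of each cell position into a
    disease-membership feature, and a linear support vector machine on the
    concatenated memberships), the Exp-seg semi-automatic expanding
    segmentation of lesions with slice-to-slice propagation, stratified
    repeated k-fold cross-validation with ACC/SEN/SPE/AUC reporting, and a
    synthetic phantom generator producing cohorts with ground-truth lesion
    masks for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    MASS,
    EBImage,
    e1071,
    pracma,
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
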