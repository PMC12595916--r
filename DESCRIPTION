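Package: sliceprop
Title: Incremental 2D Self-Labelling for Volumetric Segmentation from a
    Single Annotated Slice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains compact 2D U-Net segmentation models for 3D medical
    volumes when only the central slice of each training volume carries a
    manual annotation. Starting from a model fitted to the central slices,
    confidence-filtered pseudo-labels are propagated symmetrically outwards
    through each volume while the network is fine-tuned on the growing pool
    of labelled slices. Includes a 3D phantom generator for fully
    reproducible experiments, slice preprocessing utilities, volumetric
    overlap metrics (Dice, IoU, sensitivity, specificity) and the
    95th-percentile Hausdorff surface distance, plus end-to-end experiment
    drivers comparing central-slice-only training, incremental
    self-labelling, and a random-expansion ablation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
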