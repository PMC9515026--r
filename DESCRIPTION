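Package: patchpyramid
Title: Hierarchical Patch-Based Multiscale 3D Convolutional Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-to-fine semantic segmentation of 3D computed tomography
    volumes with a stack of small U-Nets operating on nested cubic patches of
    fixed voxel matrix but exponentially decreasing physical size. Input
    Hounsfield units are expanded into window-sensitive feature channels
    instead of being normalised, coarse-scale logits are forwarded as extra
    input channels to finer scales, and volumetrically small structures are
    trained with a top-K binary cross-entropy loss. Includes a synthetic CT
    phantom generator emulating bones, thin plates, air cavities, tubular
    canals and millimetric foramina; promising-patch descent inference; and a
    per-label evaluation suite (Dice, surface Dice at a distance tolerance,
    95th-percentile Hausdorff distance, average symmetric surface distance)
    backed by an exact Euclidean distance transform.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
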