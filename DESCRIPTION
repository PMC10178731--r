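Package: vasc3d
Title: 3D Reconstruction and Branching Analysis of Blood Vessels from Serial
    Histological Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs three-dimensional vascular models from ordered stacks
    of stained serial tissue sections. Provides vessel segmentation (block-wise
    Otsu baseline and a trainable U-net-style convolutional network), coarse
    mutual-information affine registration over an image pyramid, unsupervised
    deformable refinement with a flow-field network trained under a
    bidirectional local normalized cross-correlation loss, inter-slice mask
    interpolation to near-isotropic voxels, topology-preserving 3D
    skeletonization with branch-graph statistics, and overlap/similarity
    evaluation metrics (pairwise and sequence-wide dice, SSIM). Includes a
    synthetic phantom generator producing branching-tube volumes, stain-like
    renders and recorded per-slice misalignments, so the full pipeline can be
    validated end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    igraph,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
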