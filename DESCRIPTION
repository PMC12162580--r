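Package: apexseg
Title: Orbital Apex CT Phantoms, Attention-Augmented U-Net Segmentation and
    Detection Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for desk-scale study of optic-canal fracture detection and
    orbital-apex anatomy segmentation on CT-like images. Provides a seeded
    synthetic phantom generator emulating axial orbital-apex slices (optic
    canal, internal carotid artery, sphenoid sinus, optional fracture
    lesions with four-category bounding boxes), a U-Net model family whose
    skip connections can carry selective-kernel convolution modules or
    transformer encoder blocks, a deterministic CPU training loop, the full
    segmentation (IoU/Dice/mIoU/mDice) and detection (precision/recall/F1,
    PR curve, AP/mAP at IoU 0.5, ROC AUC, paired comparison) evaluation
    calculus, readers and writers for YOLO-style box annotations, polygon
    annotations, PNG and NIfTI images, and an ablation harness comparing
    the four model variants under shared seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    RNifti,
    jsonlite,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
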