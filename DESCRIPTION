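Package: caspnet
Title: Hybrid Vision-Transformer and CSP/SPPF Network for Cervical Cell Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and interrogates CASPNet, a hybrid image classifier
    for Pap-smear cervical cell crops that feeds a ViT-Base style token encoder
    into YOLO-style cross-stage-partial (CSP) and spatial-pyramid-pooling-fast
    (SPPF) convolutional blocks through a parameter-free token-to-spatial
    reshape. Includes the full forward and backward passes written on base R
    linear algebra, AdamW with decoupled weight decay, a one-cycle cosine
    learning-rate policy, deterministic stratified dataset splitting,
    on-the-fly augmentation, confusion-matrix/ROC evaluation, Grad-CAM
    explainability at the SPPF output, parameter/FLOP accounting for ablation
    variants, and a synthetic five-class cell-image fixture generator so the
    whole pipeline is testable without any dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    png,
    jpeg,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
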