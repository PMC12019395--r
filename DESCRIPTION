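Package: plaqueseg
Title: Artery and Atherosclerotic Plaque Segmentation for Oil-Red-O Stained Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage pipeline for quantifying atherosclerotic plaque in
    Oil-Red-O stained whole-slide images of murine aortic roots. Stage one
    proposes a bounding box for the aortic root and crops the slide to it.
    Stage two segments the arterial cross-section with small encoder-decoder
    networks trained under a combined Jaccard, Tversky and binary cross-entropy
    loss, including snapshot ensembles harvested with a cyclic learning rate
    and an alpha-overlap mask-combination strategy that trades false positives
    against false negatives. Stage three segments lipid-stained plaque inside
    the arterial wall with an unsupervised W-Net trained by alternating
    reconstruction and soft normalized-cut objectives, preceded by statistical
    color transfer and followed by morphological post-processing. Downstream
    analysis computes segmentation metrics, per-mouse plaque areas, and group
    statistics. A synthetic slide generator with known ground truth makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
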