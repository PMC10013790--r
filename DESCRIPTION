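Package: wheatseg
Title: Semi-Self-Supervised Wheat Head Segmentation from a Handful of Annotated Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds dense-pattern semantic segmentation models for wheat head
    (spike) images using very little manual annotation. From one or two
    annotated video frames it extracts real head cutouts and same-shaped
    "fake" cutouts from head-free regions, composites them onto background
    frames to synthesize large computationally annotated datasets, and trains
    a U-Net style encoder-decoder with a combined binary cross-entropy and
    Dice loss. Three staged domain-adaptation steps (full-circle rotations of
    the annotated frames, pseudo-labeling of unlabeled frames, and few-shot
    fine-tuning) bridge the gap between synthetic and real imagery.
    Includes majority-vote photometric test-time augmentation, Dice/IoU
    evaluation with per-domain reporting, and a procedural field-image
    simulator that generates fully annotated fixtures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
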