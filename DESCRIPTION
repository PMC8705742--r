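Package: skelgait
Title: Self-Supervised Gait Representation Learning from Tracked 2D Skeletons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for turning tracked 2D human pose sequences (COCO-17
    keypoints) into anonymized, normalized gait samples and learning
    identity-discriminative gait embeddings without manual labels. Implements
    tracklet quality filtering (confidence, feet visibility, length, leg
    velocity), stature-invariant skeleton normalization, stochastic skeleton
    sequence augmentation (temporal crop, pace change, mirroring, dropout), a
    spatio-temporal graph-convolutional encoder with a learnable
    edge-importance mask, supervised contrastive pretraining on tracklet
    labels, cross-view gallery/probe retrieval evaluation, and a parametric
    2D gait simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
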