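Package: mexpress
Title: Micro-Expression Spotting and Recognition from High-Speed Face Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detection (spotting) and recognition of facial micro-expressions
    in high-frame-rate video from normalized frame-difference motion
    descriptors. The face is covered by ten landmark-anchored square cells
    that approximate the territories of the facial expression muscles; a
    per-pixel motion-magnitude image (the absolute difference to a frame half
    a micro-expression duration earlier, normalized by the absolute
    difference to a near frame) drives both a boosted decision-tree
    per-frame spotter with interval post-processing and apex extraction, and
    a three-class (positive/negative/surprise) recognizer based on per-cell
    weighted-centroid displacements scored under per-class bivariate
    Gaussian models. Includes a deterministic synthetic face-video simulator
    with annotated micro-expression events so the full pipeline, including
    leave-one-subject-out evaluation, is testable without access to licensed
    micro-expression databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    rpart,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
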