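Package: polypatt
Title: Attentional Feature Fusion for Endoscopic Polyp Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a serial position-and-channel attention block for
    convolutional detection necks (local soft enhancement, directional average
    pooling, soft pooling with exponential activation weights), a multi-scale
    attentional feature fusion neck, a minimal single-class anchor-based
    reference detector with mosaic augmentation and a freeze/thaw training
    schedule, VOC-style detection metrics (precision, recall, F1, AP@0.5),
    and a seeded generator of synthetic endoscopy-like scenes with exact
    ground-truth boxes. All tensor operators are pure R with a small
    reverse-mode automatic differentiation core, so every computation is
    deterministic and verifiable against scalar oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
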