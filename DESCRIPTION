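Package: sdbyolo
Title: Lightweight Detector Blocks and Cost Accounting for Livestock
    Behaviour Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Operator library and model assembler for a lightweight
    anchor-free behaviour detector targeting four livestock postures
    (stand, lie, eat, drink).  Implements the bespoke building blocks of
    the SDB-YOLO family -- a shared-kernel dilated convolution pyramid
    (FPSC), cross-stage blocks built from ghost feature generation and
    expert-kernel dynamic convolution (C3_GDConv), convolutional block
    attention (CBAM), and a grouped-stem detection head with distribution
    focal box decoding (EfficientHead) -- together with an analytic
    parameter/FLOP profiler, detection metrics (precision, recall, mAP),
    a joint image/label augmentation suite, and a synthetic deer-pen
    scene generator with a desk-scale training loop.  Models are
    assembled from declarative YAML layer graphs; every published
    ablation variant of the architecture can be built and profiled.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
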