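Package: mgayolo
Title: Lightweight Ghost-Attention YOLO Networks for Apple Leaf Disease Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements MGA-YOLO, a lightweight one-stage object detector for
    apple leaf disease diagnosis, as a reusable toolkit: Ghost-module cheap
    convolutions, convolutional block attention (CBAM) and its squeeze-excitation
    and coordinate-attention alternatives, inverted residual bottlenecks with
    attention (MBConvA), CSP stages built from any of these, an extra stride-64
    prediction head, and GELU activations. Models are assembled from declarative
    configurations covering the full ablation ladder from the YOLOv5s baseline to
    MGA-YOLO, with an exact parameter and FLOPs profiler, anchor-based decoding
    and non-maximum suppression, COCO-style detection metrics (AP50,
    mAP@[.5:.95], confusion matrices), annotation I/O in YOLO-txt, Pascal VOC
    XML and COCO JSON formats, mosaic and photometric/affine augmentation, a
    one-cycle cosine learning-rate schedule with SGD training, and a seeded
    synthetic generator of multi-leaf scenes so the whole pipeline is testable
    without the original dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
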