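Package: fruityield
Title: Multi-Scale Fruit Detection and Yield Estimation with a GIoU Position Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for counting red (mature) and green
    (immature) fruit in plant-factory imagery with a multi-scale
    grid-based convolutional detector. Implements generalized
    intersection-over-union (GIoU) box overlap and the GIoU position
    loss alongside the classical Euclidean position loss, prior-box
    estimation via K-means clustering under the 1-IoU distance,
    encoding and decoding of YOLO-style grid prediction tensors at
    three strides, greedy per-class non-maximum suppression, average
    precision and count-ratio yield-accuracy evaluation, and a
    synthetic labeled-scene generator with sparse, dense and
    leaf-occluded regimes that stands in for unavailable plant-factory
    image data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
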