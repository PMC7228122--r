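Package: otocbir
Title: Content-Based Retrieval of Otoscopy Images via Class-Score Lookup Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: A content-based image retrieval (CBIR) pipeline for eardrum
    (tympanic membrane) images with three diagnostic categories: middle ear
    effusion, normal, and tympanostomy tube. Any convolutional neural network
    trained for classification is converted into a retrieval system by
    projecting its pooled feature vectors through the final fully-connected
    weights into per-image class-score vectors; stacking these rows yields a
    lookup table searched by Chebyshev or cosine nearest-neighbour queries.
    Includes a deterministic synthetic otoscopy-image generator for offline
    testing, region-of-interest and timestamp preprocessing, affine data
    augmentation with class balancing, a CPU-trainable tiny CNN backbone with
    frozen convolutional layers, handcrafted-feature (HSV histogram, colour
    autocorrelogram, colour moments, Gabor wavelet) KNN and SVM retrieval
    baselines, and a stratified k-fold evaluation harness reporting retrieval
    accuracy, precision, recall and F1 at several retrieval depths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
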