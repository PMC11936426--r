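Package: ngndgnet
Title: Rational-Tail Activation Networks with Gradient-Based Saliency for
    Dermoscopy-Like Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the NGNDG activation function family (linear for
    nonnegative inputs, a vanishing rational tail for negative inputs) with
    its analytic derivatives, a multi-branch convolutional network for
    seven-class skin-lesion image classification built and trained entirely
    in R (hand-derived backpropagation, sparse categorical cross-entropy,
    Adam and RMSprop optimizers, plateau learning-rate decay), Grad-CAM and
    Grad-CAM++ class-discriminative saliency maps in which the rectification
    and pixel-weight formulas use the NGNDG activation, per-class evaluation
    metrics (confusion matrix, precision, recall, F1, one-vs-rest AUC), and
    a seeded generator of synthetic dermoscopy-like images so the whole
    pipeline runs without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
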