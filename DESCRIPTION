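Package: emoco
Title: Momentum-Contrast Representation Learning for Animal Emotion Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised contrastive representation learning for
    image-based animal emotion analysis. Implements a momentum-contrast
    (MoCo) training pipeline with a FIFO feature queue, an exponential
    moving average key encoder, CIFAR-recipe residual network encoders
    with split batch normalization, two-view contrastive augmentation,
    and a temperature-weighted K-nearest-neighbour monitor classifier,
    together with an in-batch NT-Xent (SimCLR-style) variant with a LARS
    optimizer and a supervised residual-network baseline. Includes a
    generator for balanced synthetic emotion-image datasets standing in
    for withheld animal photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    EBImage,
    jsonlite,
    yaml,
    ggplot2,
    rlang,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
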