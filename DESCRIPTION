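Package: skintex
Title: Simultaneous Wrinkle and Pore Segmentation for Facial Skin Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for morphological facial-skin analysis: shape-prior texture
    maps that refine coarse manual annotations into continuous ground truth for
    wrinkles (Gaussian-normalized dark-edge enhancement) and pores
    (Laplacian-pyramid band-pass), a compact encoder-decoder segmentation
    network with bottleneck spatial attention, additive attention gates on skip
    connections and zero-padded inputs for implicit positional learning,
    classical Frangi-vesselness and high-pass/k-means baselines, IoU
    evaluation, and a deterministic synthetic facial-skin image generator used
    as the test bed for every stage. The neural network (forward, backward,
    Adam) is implemented in R with RcppArmadillo compute kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
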