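Package: karyoCycle
Title: Karyogram Enhancement with Cycle-Consistent Adversarial Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for enhancing clinical G-banded karyogram images with an
    unpaired image-to-image translation model. A karyogram is cut into its 23
    chromosome-pair tiles, each tile is enhanced by a cycle-consistent
    generative adversarial network trained on unpaired corpora of poor- and
    excellent-quality tiles, and the enhanced tiles are reassembled into a
    karyogram. Includes a synthetic banded-karyogram generator with a
    parametric degradation operator for building training corpora and
    evaluation fixtures, PSNR/SSIM quality metrics with a degradation-based
    evaluation protocol, histogram-equalization and block-matching (3D
    collaborative filtering, hard-threshold stage) baselines, rating-study
    statistics based on one-tailed paired t-tests, and a structural-fidelity
    check that enhancement neither completes missing chromosomal material nor
    invents new material.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tools,
    png,
    tiff,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
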