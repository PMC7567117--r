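Package: cryodenoise
Title: Self-Supervised Denoising of CryoEM Micrographs and CryoET Tomograms
Version: 0.1.0
Authors@R:
    person("cryodenoise", "maintainers", email = "cryodenoise@example.org",
           role = c("aut", "cre"))
Description: Learn convolutional denoising models for cryo-electron microscopy
    micrographs and cryo-electron tomography volumes without clean references,
    by training on paired even/odd movie-frame sums under the Noise2Noise
    objective. Provides MRC2014 image input/output, even/odd pair generation
    and dose fractionation from movie stacks, affine, fully convolutional and
    U-net denoiser architectures (2D and 3D) with deterministic Adagrad
    training, seam-free tiled inference for arbitrarily large images, two
    signal-to-noise estimators (region-based and split-frame cross-correlation),
    low-pass baselines, dose-titration curves, and a synthetic movie generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    optparse,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
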