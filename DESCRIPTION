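Package: reggan
Title: Registration-Corrected Adversarial CBCT-to-Synthetic-CT Translation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Translates cone-beam CT (CBCT) slices into synthetic CT (sCT)
    images with a registration-corrected generative adversarial model
    (RegGAN): a residual-block generator, a U-Net registration network that
    absorbs spatial label noise between unpaired-in-time modalities via a
    dense displacement field, and a patch discriminator, trained with a
    correction (L1-after-warp) loss, a displacement smoothness penalty and a
    least-squares adversarial loss. Includes Hounsfield-unit preprocessing
    (clipping, [-1,1] normalization, resampling), image-quality evaluation
    (MAE, MSE, PSNR, SSIM, restricted-range HU histograms, nonparametric
    group comparison), dose-volume-histogram statistics with dose-difference
    rates and pass rates for planning target volumes, and a multi-accelerator
    head-and-neck phantom simulator with accelerator-specific CBCT
    degradation profiles for end-to-end exercise of the method.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
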