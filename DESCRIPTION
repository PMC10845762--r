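Package: sinomar
Title: Sparse-View and Metal Artifact Reduction for CT Specimen Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage artifact suppression for computed tomography of
    resected tissue specimens scanned with few projection views and an
    embedded metallic marker. The sinogram is completed by metal-track
    removal, angular up-sampling, linear-interpolation initialization and
    patch-based synthesis with a modified U-Net; the filtered-backprojection
    reconstruction is then denoised by a modified residual U-Net in the image
    domain and the segmented metal is reinserted. Includes a parallel-beam
    line-integral projector, filtered backprojection and penalized weighted
    least-squares reconstruction, an artifact-simulation module that
    generates paired training data from piecewise-constant soft-tissue
    phantoms, small trainable convolutional networks, and the RMSE, PSNR,
    SSIM and CNR evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
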