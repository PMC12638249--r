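Package: inif
Title: Implicit Neural Image Field Compression for Multidimensional Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossy compression of multidimensional microscopy images (up to
    T, C, Z, Y, X axes) by fitting a small sinusoidal coordinate network
    (SIREN) to pixel values, sized so that the serialized file respects a
    user-chosen compression ratio. Includes task-guided training losses
    (soft intersection-over-union segmentation guidance and a perceptual
    patch loss), a hybrid mode that codes the residual over a classic codec,
    a self-describing binary container, pixel-addressable decoding (slices,
    strided previews, masks, arbitrary index sets), PSNR/SSIM quality
    metrics, and a seeded synthetic microscopy image generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
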