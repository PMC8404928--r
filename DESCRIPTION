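Package: sdmd
Title: Lossy Image Compression with Spline-Encoded Dense Medial Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encodes 8-bit grayscale and colour raster images as per-layer
    medial axis transforms of threshold sets, each skeletal branch fitted
    with a minimal-control-point B-spline, and decodes them by disc-union
    reconstruction with inter-layer interpolation.  Includes adaptive
    upper/lower layer polarity selection, perceptual per-channel YCbCr
    parameter scaling, border Y-structure removal, super-resolution
    rendering from the same encoding, salient-region island control, a
    compact binary container, SSIM quality metrics and deterministic
    synthetic benchmark image generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    splines,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
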