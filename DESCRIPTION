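Package: ctcolor
Title: Colorization of Grayscale Lung-CT-Like Images by Chroma Regression
    and Exemplar Style Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Colorizes grayscale medical-style images two ways: an automatic
    encoder/decoder convolutional network that predicts the chroma channels
    of a perceptual color space (CIE Lab or CIE Luv) from the luminance
    channel, and an exemplar method that transfers the color and texture
    statistics of a reference image onto the target by iterative
    minimization of Gram-matrix feature losses. Includes exact CIE color
    space conversions, a compact CPU convolutional-network engine with
    backpropagation, full-reference image quality metrics (MSE, PSNR, SSIM),
    and seeded procedural generators of meat-like color textures and
    lung-CT-like grayscale phantoms so that the entire pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jpeg,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    farver,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
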