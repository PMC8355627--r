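Package: sectionalign
Title: Supervised Multimodal Registration of Histological Section Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for supervised 2D registration of multimodal histological
    section images, such as gene-expression (ISH) sections against a Nissl
    reference. Provides a dense displacement-field algebra (warping,
    composition, numerical inversion by scattered-data interpolation,
    Jacobian folding analysis), thin-plate-spline landmark interpolation, a
    two-stage affine-plus-elastic registration network trained with an image
    error, a normalized squared endpoint error, and a perceptual similarity
    loss computed on the displacement-field components, elastic and
    photometric data augmentation, synthetic multimodal section-pair
    generation with ground-truth deformations, stratified and gene-holdout
    dataset splits, and hierarchical pixel-weighted Dice evaluation in
    moving space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tibble,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
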