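Package: helaseg
Title: Semantic Segmentation of HeLa Cells in Serial Block-Face Electron Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for four-class semantic segmentation (background, cell,
    nuclear envelope, nucleus) of HeLa cells imaged by serial block-face
    scanning electron microscopy. Provides a classical image-processing
    segmentation pipeline (Canny edges, edge-complement superpixels,
    morphological selection with slice-to-slice propagation), a synthetic
    EM phantom generator with exact ground truth, patch-pair training-set
    construction under several strategies, a from-scratch four-class U-Net
    trained by backpropagation with the Adam optimiser, class-wise
    morphological post-processing, and per-slice accuracy and Jaccard
    evaluation with slice-range summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
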