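Package: maskaug
Title: Annotation-Preserving Image Augmentation for Bioimage Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data augmentation engine for bioimage analysis that regenerates
    annotations alongside images. Supports object classification, localization,
    detection, semantic segmentation and instance segmentation on 2D images as
    well as z-stacks and videos decomposed into frames. Position-variant
    techniques (flips, rotations, translations, crops, rescaling, shears,
    elastic deformations) are propagated to annotations by warping binary masks
    with the exact geometric plan applied to the image; position-invariant
    techniques (blurs, noise, intensity and colour adjustments) reuse the input
    annotation verbatim. Datasets are read and written in standard formats
    (folder-per-class, PASCAL VOC XML, YOLO text, paired label masks, COCO
    JSON, paired multi-page TIFF stacks), augmentation runs are configured by a
    JSON file with linear and power generation modes, and a command-line
    interface is provided.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    tiff,
    png,
    xml2,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
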