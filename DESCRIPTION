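Package: thgq
Title: Quantification of Brain-Tissue Cellularity in Third Harmonic Generation Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification workflow for label-free third harmonic
    generation (THG) microscopy images of fresh brain tissue. Images are
    contrast-enhanced and denoised, segmented into dark holes (cell bodies),
    bright objects (nuclei, neuropil fibers, lipofuscin granules) and
    background by a three-phase region-competition segmentation anchored to
    the intensity extremes, faint round nuclei are rescued from the
    background by a gradient-directed circular Hough transform, and objects
    are filtered and classified by size and sphericity. Per-image density
    features (percentage of space of cells and nuclei, neuropil perimeter
    density) feed a two-threshold normal/tumor classifier for mapping glioma
    infiltration across stitched image mosaics. Includes a synthetic phantom
    generator with exact ground-truth masks, paired-fluorescence validation
    utilities, mosaic stitching and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
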