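Package: ecmscore
Title: Layer-Wise Quantification of Tumor-Cell-Induced Extracellular
    Matrix Remodeling in 3D Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how tumor-cell clusters remodel a fluorescently
    labeled fibroblast-derived 3D extracellular matrix from multi-channel
    confocal z-stacks. Partitions stacks into top/middle/bottom layers by
    fibronectin coverage, segments cell-containing versus cell-devoid
    regions from the nuclei channel, computes the high/low intensity
    area-ratio remodeling score per layer and channel on maximum-intensity
    projections, classifies degrader versus accumulator/contractor
    phenotypes, and runs the accompanying statistics (log-scale one-way
    ANOVA against untreated controls with Benjamini-Hochberg false
    discovery rate control). Includes a synthetic stack generator with
    known ground truth for validation, multi-page TIFF input/output,
    orthogonal XZ reslicing, and pseudo-colored layer reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    rlang,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
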