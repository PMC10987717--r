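Package: organoidquant
Title: Quantification of Neural Rosettes, Marker Intensity, Colocalization
    Volumes and Single-Cell Screens in Cerebral Organoid Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for fluorescence-image and single-cell
    quantification in cerebral organoid studies. Builds Body and Ribbon
    regions of interest from hand-drawn rosette boundaries using physical-unit
    (micron) erosion and dilation, measures mean channel intensity, area and
    aspect ratio; quantifies punctate markers with top-hat background
    subtraction and Otsu foreground selection; computes thresholded
    colocalization volumes (TVC) across channel pairs in 3D stacks; applies
    single-cell QC filtering, fixed-size downsampling, cluster-aggregate log2
    sample ratios, fold-change gene selection, enrichment-score cutoffs and a
    binomial overrepresentation test; and runs the Shapiro-Wilk / one-way
    ANOVA / Tukey group-comparison chain with isogenic-control pooling. A
    seeded synthetic-data generator plants known ground truth for every stage
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
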