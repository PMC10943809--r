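Package: colordepth
Title: Color Depth MIP Encoding, Search and Cross-Modal Neuron Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Encodes aligned 3D neuron data (EM skeletons in SWC format,
    segmented light-microscopy channels) as color depth maximum intensity
    projections (CDMs), where pixel color encodes the depth of the brightest
    voxel. Provides the CDM pixel-overlap search kernel with translation and
    mirror-flip augmentation, a uni-directional shape-matching re-scoring that
    penalizes unsupported EM pixels in XY and Z, direction-selective local
    thresholding (DSLT) segmentation of multi-neuron channels, an all-vs-all
    precompute with driver-line grouping and capping, and a versioned static
    JSON bucket layout for serving precomputed match tables. Includes a
    synthetic-data generator producing aligned toy EM/LM datasets with ground
    truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
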