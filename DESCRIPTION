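Package: rcpdecode
Title: Spot Detection, Barcode Decoding and Cell Quantification for In Situ Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for hybridization-based in situ
    sequencing (HybISS) experiments read out by rolling circle amplification.
    Covers maximum-intensity projection, normalized cross-correlation tile
    stitching and round alignment, white top-hat filtering, intensity/size
    thresholded spot calling with a channel-purity quality score, sequential
    and combinatorial barcode decoding with a distance-penalized quality
    score and Q > 0 filtering, DAPI-based watershed cell segmentation with
    spot-to-cell assignment, density-based low-magnification quantification,
    and construction, filtering, normalization and Leiden clustering of the
    cell-by-gene expression matrix. Includes a synthetic-experiment
    simulator that renders multi-round, multi-channel, multi-tile image
    stacks with full ground truth so every stage is testable without
    microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    Matrix,
    igraph,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
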