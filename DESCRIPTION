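Package: SporeHull
Title: Convex-Hull Morphometry of Basidiospore Silhouettes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative morphometry of fungal basidiospores in side view,
    built around a convex-hull concavity statistic (the suprahilar-depression
    percentage, i.e. 100 times one minus silhouette solidity) that separates
    otherwise overlapping Mediterranean Cyanoboletus species. Provides a
    parametric synthetic silhouette generator with species presets and
    hierarchical population sampling, segmentation and subpixel contour
    extraction from binary spore masks, Feret-based length/width measurement,
    classical spore descriptors (Q ratio, area, rotation-ellipsoid volume),
    collection-level "(min) mean +/- sd (max)" summaries, nonparametric and
    parametric two-sample comparisons with exact small-sample Mann-Whitney
    enumeration, isoprobability ellipses and kernel density estimates of the
    length-width cloud, a deterministic dichotomous microscopy key with full
    decision-path audit, arsenic content summaries with hyperaccumulation
    flagging, and an alignment site-category tally utility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    MASS,
    withr,
    isoband,
    EBImage,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Classification, CellBiology
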