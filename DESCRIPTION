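Package: karstbeta
Title: Abundance-Based Beta-Diversity Partitioning Across Sampling Grains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Partitions pairwise Bray-Curtis dissimilarity between forest
    census quadrats into balanced-variation and abundance-gradient
    components, and relates the components to topographic gradients and
    spatial structure.  Provides a synthetic generator for a gridded
    karst (fengcong-depression) forest-dynamics plot with two linked
    censuses, quadrat aggregation at multiple sampling grains with
    margin-discard rules, per-quadrat topographic variables (elevation,
    slope, convexity, aspect, wetness index, altitude above channels),
    Mantel permutation tests with Spearman correlation, distance-based
    Moran's eigenvector maps (dbMEM/PCNM), and variation partitioning of
    community dissimilarity into pure-habitat, spatially-structured
    habitat, pure-space and undetermined fractions via distance-based
    redundancy analysis with forward selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
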