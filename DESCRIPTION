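Package: immunospat
Title: Spatial Immune Interactome Analysis for Multiplexed Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for spatial analysis of the tumor immune
    microenvironment from multiplexed immunofluorescence cell tables.
    Provides dual-threshold marker gating into an immune phenotype taxonomy,
    nucleus-label post-processing (isotropic label expansion, minimum-area
    filtering, centroid extraction), cross-type nearest-neighbour G-function
    dyad scoring with area-under-the-curve dichotomization, radius-bounded
    cross pair counts for cluster detection, region-stratified composition
    summaries, and cohort-level inference (exact Wilcoxon rank-sum,
    repeated-measures ANOVA on log-transformed percentages, false discovery
    rate control). A synthetic-tissue generator produces wedge geometries,
    marked point patterns with controllable cross-type attraction, marker
    intensities and rasterized label masks so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
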