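Package: flyatlas
Title: Cross-Species Comparison of Drosophila Blastoderm Gene Expression Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative comparison of cellular-resolution gene
    expression atlases of the Drosophila blastoderm across species. Provides
    S4 containers for per-embryo pointclouds (nucleus coordinates, expression
    levels and surface triangulation) and species-level atlases over six
    developmental time cohorts; a synthetic-atlas generator with recorded
    ground truth; atlas construction from registered pointclouds with
    per-embryo gain/offset normalisation and an inter-embryo variability
    quality metric; embryo morphology summaries (mesh surface area, local
    nuclear density in 15 micron disks, cylindrical density maps, egg length
    and shape profiles); threshold-based binary cell-type analysis with
    combination filtering and gene-count dynamics; spatially matched squared
    Euclidean expression distance scores with local best-match search and
    inverse-distance-weighted displacement fields; and monotone developmental
    time-point matching between species with hourglass divergence curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    RANN,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
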