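Package: belapol
Title: Spatial Polarization and Clonality Analysis for Bilayered
    Embryo-Like Aggregates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies spatial patterning in two-compartment stem-cell
    aggregates (an epiblast-like core surrounded by a visceral-endoderm-like
    layer) from segmented nucleus tables or label-mask images.  Computes
    intensity-weighted polarization vectors of expression domains normalized
    by the compartment radius of gyration, builds a permutation null by
    shuffling measured intensities across nucleus positions, classifies
    polarized structures against a percentile of that null, measures the
    angle between two expression domains, and scores the clonal composition
    of marker-positive cell nests.  A synthetic-data generator with von Mises
    angular expression domains and known ground truth makes the whole
    pipeline testable without microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    igraph,
    jsonlite,
    mgcv,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
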