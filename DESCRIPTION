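Package: medscan
Title: Association Mapping and QTL Hotspot Analysis for Structured Wheat
    Landrace Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for structured germplasm
    collections of bread wheat landraces: genotype quality control,
    REML/BLUP adjustment of augmented field designs, climate phenotypes
    from country-of-origin tables, mixed-linear-model association scans
    (PCA + kinship) for phenology, environmental and eigenvector traits,
    consolidation of marker-trait associations into QTL hotspots via a
    per-cM overview index, classification of subpopulation allele-frequency
    differentiation, and candidate-gene extraction with a differential
    expression filter.  Includes a Balding-Nichols structured-population
    simulator so every stage can be exercised and validated on synthetic
    collections with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    withr,
    lme4,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
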