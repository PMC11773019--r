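Package: hcsprotect
Title: High-Content Screen Analysis for Photoprotective miRNA Discovery
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for arrayed miRNA-mimic high-content imaging
    screens in light-stressed photoreceptor-like cells. Provides a seeded
    synthetic-data generator with known ground truth (384-well plate layouts,
    nuclei images, well-level dying fractions, trypan-blue count tables),
    nuclei segmentation and healthy/dying classification, per-plate quality
    control and Z scoring against light-exposed control wells, replicate
    aggregation with coefficient-of-variation and annotation filtering for
    hit shortlisting, and two-way ANOVA analysis of secondary viability
    assays with light/dark fold-change normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
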