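Package: kineticnet
Title: Kinetic Regulatory Networks from Chromatin Accessibility and
    Nascent Transcription Time Courses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Infers temporally resolved gene regulatory networks from
    replicated ATAC-seq and PRO-seq time courses. Peaks are normalized,
    tested for differential accessibility with a negative-binomial Wald
    test, and assigned to five kinetic response classes; position weight
    matrices are scanned with exact dynamic-programming p-values to
    predict factor binding; rule sets turn accessibility, motif,
    proximity, and covariation evidence into directed trans-edges
    (factor to regulatory element) and cis-edges (regulatory element to
    gene) with binding, dissociation, and attenuation attributes. A
    two-compartment model of RNA polymerase II occupancy (initiation,
    premature termination, pause release, elongation) converts pause and
    gene-body densities into rate-constant fold-changes and pause
    residency times. A synthetic time-course generator with planted
    ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    GenomicRanges,
    IRanges,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
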