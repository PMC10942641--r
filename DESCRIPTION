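Package: clonetrackr
Title: Clonal Barcode Tracking and Stem-Cell Activity Quantification for
    Ex Vivo Expansion Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing lentiviral cellular-barcoding experiments
    that track clonal hematopoietic stem cell (HSC) behaviour through ex
    vivo expansion cultures and competitive transplantation. Provides a
    generative simulator of heterogeneous clonal expansion, recipient
    splitting and amplicon sequencing (FASTQ plus ground truth); barcode
    extraction from FASTQ into count matrices; the background-filtering,
    multi-parental exclusion and reads-per-million normalisation pipeline;
    clone-size, sharing and distribution statistics with a truncation-aware
    lognormal heterogeneity estimator and parametric bootstrap;
    repopulating-unit (RU) quantification of chimerism data with
    expansion-fold arithmetic; and division counting from dye-dilution
    (CellTrace-style) intensities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
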