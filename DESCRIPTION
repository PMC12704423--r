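Package: oomics
Title: Multi-Omic Analysis of Oocyte Methylomes, Proteomes and Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for multi-omic analysis of mouse germinal-vesicle oocytes:
    differential protein abundance from raw label-free intensity matrices
    (log2 transformation, group fold changes, Student t-tests with
    Benjamini-Hochberg control), single-cell post-bisulfite (scPBAT)
    methylome quality control with a three-criterion somatic-contamination
    screen, 100-CpG tiling, hypo/hypermethylated domain segmentation,
    chi-square differential methylation of tiles and imprinted germline
    DMRs with coverage filters, marker-based NSN/SN oocyte staging with
    stated QC bounds, and cross-omic set-overlap and fold-change
    integration. A seeded synthetic-data module generates bimodal oocyte
    methylomes with planted knockout effects and somatic contamination,
    log-normal proteomes, and negative-binomial transcriptomes with ground
    truth, so every stage of the pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
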