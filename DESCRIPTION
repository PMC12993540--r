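Package: phagemark
Title: Marker-Based Discovery and Tracking of Conserved Phage Families in Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and spatio-temporal tracking of conserved phage gene
    families (large-terminase, TerL, markers) in translated metagenomes.
    Implements signature-based greedy clustering of a reference library
    against a metagenome, a marker-discovery filtering cascade
    (annotation, signature-size and identity gates, cross-dataset
    conservation screen, redundancy removal, full-length marker
    selection), three-state presence calling with prevalence and
    co-occurrence summaries across cohort subjects and body habitats, a
    temporal persistence statistic for consecutive visits, CODEHOP-style
    degenerate primer design with degeneracy, melting-temperature and
    secondary-structure diagnostics, an amplicon read-processing pipeline
    (pair joining, Phred filtering, barcode demultiplexing, OTU
    clustering), and preparation and export of alignment matrices for
    external phylogenetic tools. A synthetic-data module generates
    reference libraries, planted metagenomes, longitudinal cohorts and
    barcoded amplicon runs with known ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
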