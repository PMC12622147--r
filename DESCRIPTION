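Package: clonotrace
Title: Clonal Lineage Tracing, Targeted Genotyping and Copy-Number
    Analysis for Barcoded Kras-G12D Tumor Models
Version: 0.1.0
Authors@R:
    person("clonotrace", "developers", email = "clonotrace@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing lineage-traced pancreatic tumor models in
    which every malignant clone carries a synonymous-mutation barcode
    embedded in the oncogenic Kras-G12D coding sequence. The package
    enumerates and samples the barcode design space, simulates
    ground-truthed tumors with paired targeted sequencing reads and
    single-cell whole-genome bin counts, calls per-cell clonotypes with
    allelic-imbalance classification from barcode sequencing, quantifies
    Kdm8 transcripts with zero imputation for genotype inference, builds
    equal-mappability copy-number bins with GC correction, and provides
    the TSS proximal/distal annotation and exact contingency statistics
    used for incidence tallies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
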