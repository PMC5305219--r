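Package: chromakin
Title: Linking Ligand-Induced SMAD2 Chromatin Binding to Transcriptional Kinetics
Version: 0.1.0
Authors@R:
    person("chromakin", "maintainers", email = "maintainers@chromakin.dev",
           role = c("aut", "cre"))
Description: An integrative ChIP-seq/RNA-seq analysis pipeline for
    Activin/NODAL-SMAD2 signalling time courses. Implements median-of-ratios
    count normalization with a simplified negative-binomial Wald test and
    bespoke target filters, rule-based kinetic classification of regulated
    genes (induced sustained, transient induced, delayed, repressed; baseline
    on/off; direct/indirect), consensus SMAD2 peak construction and footprint
    quantification, differential RNA polymerase II occupancy calling via
    windowed tests and gene overlap ratios, strand-aware metaprofiles,
    acetylation-state stratification of binding sites, directed IUPAC motif
    scanning with tri-nucleotide shuffle backgrounds, and a synthetic-study
    generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
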