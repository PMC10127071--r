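Package: circpep
Title: Discovery and Quantification of Protein-Coding Circular RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A proteogenomic pipeline for identifying translatable circular
    RNAs (circRNAs) from back-splice junction calls and mass-spectrometry
    evidence. Builds a consensus set of back-splice junctions from multiple
    circRNA callers (CIRI2, CIRCexplorer2, find_circ dialects), assembles
    spliced circular sequences from a genome and annotation, predicts open
    reading frames on circles including rolling-circle translation across the
    back-splice junction, digests predicted proteins in silico with trypsin,
    filters peptides against a reference proteome to retain circRNA-unique
    junction peptides, maps peptide-spectrum matches back to circRNAs, and
    quantifies targeted parallel-reaction-monitoring (PRM) data as
    endogenous-to-heavy transition peak-area ratios. Includes a seeded
    synthetic-data generator that plants circles with known ORF structure,
    caller outputs, PSM tables and PRM transition tables for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
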