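Package: charaband
Title: Region-Resolved Membrane Proteome Analysis for pH-Banding Characean Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free membrane proteomics of acidic and
    alkaline surface regions of characean internodal cells, built for a
    non-genome-sequenced organism. Constructs a protein search database from
    transcriptome unigenes by six-frame translation and longest-ORF selection,
    ingests MaxQuant-style peptide evidence tables, applies contaminant/reverse
    and replicate-presence filters, computes BIN-class fraction-of-total (fot)
    spectral-count statistics with acidic/alkaline enrichment ratios, performs
    total-ion normalization, cross-treatment scaling, replicate averaging and
    proteotypic protein quantitation with Welch-test differential statistics,
    and computes protein sequence coverage. A synthetic-data generator with
    known ground truth stands in for the raw mass-spectrometry data so that
    every pipeline stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    tibble,
    tidyr,
    readr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
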