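Package: digibreak
Title: Digital DNA Double-Strand Break Mapping and CRISPR Off-Target
    Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational pipeline for PCR-free, digital double-strand
    break (DSB) sequencing. Converts aligned break-labelled reads into
    deduplicated single-nucleotide breakends (MAPQ and soft-clip
    filtering, blacklist removal, flow-cell-aware optical duplicate
    removal), maps nuclease target sites with mismatch tolerance
    (restriction enzymes and CRISPR guides), quantifies and ranks breaks
    per site with cumulative-frequency and per-cell normalisation, and
    discovers CRISPR off-target sites through a 32-condition filter
    matrix with empirical treated-versus-control false discovery rate
    selection. Includes a simulator that generates genomes, planted
    nuclease sites, per-cell break events and aligned reads with
    flow-cell metadata and machine-readable ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
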