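Package: mitobook
Title: Mitotic Gene-Bookmarking ChIP-Seq Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Re-implements, as tested and reusable components, a ChIP-seq
    analysis workflow for mitotic gene bookmarking: construction of an
    rDNA-aware reference (in-silico read tiling, exact-match masking, and
    appending the ribosomal repeat unit as its own contig), a minimal
    Poisson local-lambda peak caller with fold-enrichment tracks, a
    per-peak strand cross-correlation filter against single-position read
    stack artifacts, TSS annotation of protein-coding and lncRNA genes,
    and classification of genes by occupancy across asynchronous, mitotic
    and early-G1 cell populations integrated with a differential-expression
    significance filter. A synthetic-data module generates genomes,
    Gencode-style annotations, stranded tags with planted binding sites and
    phantom artifacts, and expression tables with known truth, so that
    every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
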