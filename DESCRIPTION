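Package: splitTE
Title: Split-Read Detection of Transposable Element Insertions and
    Chimeric TE-mRNA Transcripts from RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects de novo transposable element (TE) insertions and
    chimeric TE-mRNA transcripts from bulk RNA-seq by split-read mapping
    of 22nt read ends against a repeat-masked genome, a TE consensus
    library and an immobile-gene-element (IGE) control set, followed by
    junction clustering and quality filtering (support, window, span,
    identity, low-complexity poly-T, symmetry, coverage ratio). Calls are
    triaged into TE-mRNA fusions, two-mRNA template-switch artifacts and
    InDel/splice isoforms, with cross-sample recurrence counting and a
    rank-correlation analysis of TE transcriptional autonomy. Includes a
    seeded synthetic-data generator (genome, gene models, planted
    insertions, RNA-seq and WGS reads with the characteristic artifact
    classes) so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    yaml,
    jsonlite,
    ggplot2,
    generics,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
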