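Package: cisfoot
Title: Phylogenetic Footprinting of Degenerate Transcription-Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A conservation-based screen for cis-regulatory sites in nematode
    promoters. Scans strand-aware upstream regions of orthologous genes for
    degenerate IUPAC motifs (e.g. the CSL/LAG-1 site RTGGGAA and the FoxA site
    TRTTKRY), pairwise-aligns orthologous upstream regions, extracts conserved
    sequence blocks (at least 14 nt at 70 percent identity), calls a motif site
    conserved when its aligned block carries the motif in at least two other
    genomes, and applies a combinatorial proximity filter for composite
    two-factor sites. Includes a multi-species promoter evolution simulator
    with planted conserved, decayed and negative sites so every stage is
    testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
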