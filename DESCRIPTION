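Package: repeatkit
Title: K-mer Repeat Detection, Transposable Element Library Curation and
    Masking Benchmarks for Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-step plant-repeat annotation protocol: repeats are first
    called de novo by canonical k-mer counting and soft-masked, then
    classified by alignment against a curated, nonredundant transposable
    element (TE) library. Includes the library-curation procedure (sequence
    clustering by identity and coverage, mixed-cluster filtering, a
    Pfam-domain control benchmark with sensitivity and specificity), masking
    benchmark statistics (gene/exon/flank overlap fractions, an odds ratio
    of NLR disease-resistance locus masking, Fisher exact domain enrichment
    with false discovery rate control, canonical k-mer censuses), and a
    synthetic genome simulator with planted TE families so every pipeline
    stage can be exercised without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    rtracklayer,
    stats,
    stringi,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
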