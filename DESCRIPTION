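Package: cladetrace
Title: Quality Control and Taxonomic Tracing of Small RNA Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control, taxonomic tracing, and post-sequencing
    contamination cleaning for small RNA (miRNA) sequencing data. Reads are
    pre-processed with protocol-aware 3' adapter trimming (TruSeq/QiaSeq,
    NEXTflex, CATS), quality and complexity filtering, annotated by RNA type
    against precursor/tRNA/rRNA/artifact references with an exact-then-one-
    mismatch cascade, and traced to animal and plant clades (or species) by
    exact 20-mer matching against curated clade-specific mature miRNA
    markers. Cross-sample contamination caused by index misreading or index
    mis-pairing is removed with a strict demultiplexer that exploits the
    inline second read of the sample index. A binomial model quantifies the
    expected rate of spurious marker matches, and a seeded synthetic-data
    generator produces reads, mixtures, and multiplexed runs with full
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    stats,
    stringi,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
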