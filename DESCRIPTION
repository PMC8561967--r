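Package: capss
Title: Clone-Array Pooled Shotgun Sequencing of BAC End Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Profiles bacterial artificial chromosome (BAC) end sequences
    from indexed pooled shotgun reads of a two-dimensional plate superpool
    and anchors the clones on a reference genome. Implements the clone-array
    pooled shotgun sequencing (CAPSS) deconvolution: row-pool and column-pool
    libraries are demultiplexed by a 7-bp index, vector-insert junction reads
    are assembled into short end-sequence consensi and pool contigs are
    trimmed into long end sequences, sequences shared between a row pool and
    a column pool are assigned to the well at their intersection, and
    well-assigned end sequences are placed on a genome under a strict
    identity/coverage alignment contract with paired-end clone intervals,
    organelle screening, GFF3 output and gap-coverage accounting. A built-in
    simulator generates a synthetic genome, a HindIII-constrained clone
    array and indexed pooled paired-end reads with full truth tables, so the
    whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
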