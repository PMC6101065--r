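Package: repcon
Title: De Novo Consensus Repeat Construction from Short Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs consensus repeat sequences (transposable elements and
    other interspersed repeats) directly from unassembled short sequencing
    reads, without a reference genome or an existing repeat library. The
    pipeline counts canonical k-mers, classifies them into highly frequent and
    intermediate tiers relative to the per-copy k-mer depth, recruits
    intermediate-frequency repeat-related k-mers by similarity to the highly
    frequent ones, polishes recruited k-mers with a randomized
    position-sampling grouping scheme and frequency-weighted consensus voting,
    assembles the polished k-mers with a native de Bruijn unitig assembler,
    merges contigs on reliable suffix-prefix overlaps, collapses near-identical
    assembled repeats with union-find clustering, and scores the result against
    a reference repeat library. A planted-repeat genome and read simulator is
    included so the whole pipeline can be exercised end to end on synthetic
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
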