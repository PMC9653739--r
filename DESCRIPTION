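Package: plastinv
Title: Inversion Archaeology for Rearranged Plastid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the history of structural rearrangements
    in plastid genomes (plastomes). Implements a signed gene-block algebra for
    computing reversal distances and exhaustively enumerating minimal inversion
    scenarios between two arrangements, with filters for phylogenetic
    constraints and the 'common cause' recurrent-endpoint (hot spot) criterion;
    sequence-level detection of dispersed inverted repeats, hairpins and
    stem-loop-ligation signatures for mechanistic classification of inversion
    endpoints (stem-loop versus disruption-rescue); junction archaeology via
    parsimony ancestral-sequence reconstruction, interval-difference event
    calling (substitutions, tandem duplications, deletions, transposed and
    foreign insertions) and relative dating of duplicative transpositions; and
    a seeded generator of annotated synthetic plastomes with planted
    rearrangement events. Ships block-order fixtures encoding the five-inversion
    derivation of the Lobelia fervens/L. erinus large single-copy region.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
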