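Package: notchtrace
Title: Comparative Evolution of Notch Pathway Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative-evolutionary analysis of the Notch
    signalling pathway across metazoans, with an emphasis on lophotrochozoans.
    Classifies genes into pathway families (Notch, Delta, Jagged, Presenilin,
    Su(H), Hes/Hey-related) from protein domain-hit tables using
    domain-architecture signatures; types the mechanism of premature
    termination in derived paralogs (nonsense substitution, stop-creating
    insertion, frameshifting indels) from codon-aware pairwise alignments;
    places gene-family gains and losses on a rooted species tree by Dollo
    parsimony; builds neighbor-joining trees with bootstrap support for
    paralog-clade tests; and scores developmental expression profiles for
    similarity and complementarity between paralogs. Ships a synthetic-data
    generator that plants known truth for every analysis stage, so the whole
    pipeline is testable end to end without external genome downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
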