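Package: bchtools
Title: Comparative Sequence Analysis of BCH and CRAL_TRIO Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for distinguishing BNIP-2 and Cdc42GAP
    Homology (BCH) domains from CRAL_TRIO domains of the Sec14 protein
    superfamily. Implements dataset screening (length, long-gap and
    greedy redundancy filters), pairwise global alignment and percent
    identity statistics, distance-based Neighbor-Joining phylogenies
    with bootstrap support and clade collapsing, per-column conservation
    and sequence-logo information content, a degenerate residue-class
    motif language with the 16-position BCH hallmark motif, diagnostic
    signature-residue sets anchored to human BNIP-2 and yeast Sec14p, a
    three-way BCH / BCH-like / CRAL_TRIO classifier, and mapping of
    intron positions onto secondary-structure elements. Ships a
    synthetic family generator with known trees, planted motifs and
    conservation rates so every stage can be validated against ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
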