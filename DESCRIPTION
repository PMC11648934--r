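Package: csptyper
Title: Residue-Anchor Typing and Phylogenetic Analysis of Bacterial
    Cold-Shock Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for subclassifying bacterial cold-shock proteins (Csps)
    by diagnostic residues projected through a multiple sequence alignment:
    anchor-position mapping with trim provenance, K-A / K-E / D-E loop
    typing and N-terminal K4 flagging, neighbor-joining trees and
    bipartition-based monophyly tests, per-genome Csp distribution
    statistics with an exact/normal-approximation Mann-Whitney U test, and
    band-quantitation arithmetic (relative RNA levels, specificity scores,
    readthrough fractions, pull-down enrichment ratios). Includes seeded
    generators for cold-shock-domain-like families with planted clades,
    genome tables with planted size/GC effects, and replicate quantitation
    tables, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
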