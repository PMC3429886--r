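Package: cgrphylo
Title: Alignment-Free Phylogenetics from Chaos Game Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Chaos Game Representations (CGR) and Frequency Chaos
    Game Representation (FCGR) genomic signatures from nucleotide sequence
    sets, Euclidean and weighted-Pearson distances between FCGRs, and
    distance-based phylogenetic trees with an FCGR cell-resampling bootstrap:
    Neighbor-Joining point estimates, majority-rule consensus trees with
    branch supports, and Fitch-Margoliash style weighted least-squares branch
    lengths on a fixed topology. Includes a sequence simulator (random
    composition-controlled sequences, random additive trees, sequence sets
    evolved along a known tree) for validation, plus SVG/raster renderings of
    CGRs and FCGRs and PHYLIP/Newick interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    pracma,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite,
    png
Config/testthat/edition: 3
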