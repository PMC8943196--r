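Package: carnet
Title: Reaction-Rule Expansion and Conserved-Atom-Ratio Biochemical Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting hypothetical enzymatic reactions by applying
    generalized reaction rules encoded as bond-electron matrices to a universe
    of small molecules, for building atom-conservation-weighted
    biotransformation networks, and for searching and benchmarking metabolic
    pathways in those networks. Compounds are deduplicated by canonical
    SMILES (stereochemistry stripped, simple charge states neutralized),
    reactions are balance-checked and deduplicated by reactant/product
    structure, substrate-product edges are weighted by the conserved atom
    ratio (CAR) with a cofactor-table / maximum-common-substructure / formula
    fallback cascade, and pathways are retrieved with a deterministic Yen
    k-shortest loopless path search. Ships a small hand-verified rule library
    and a deterministic toy compound universe for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
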