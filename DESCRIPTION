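Package: rnacore
Title: Conserved-Core Clustering and Consensus Model Selection for RNA 3D Decoys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consensus selection of RNA tertiary-structure models across
    sequence homologs. Given a multiple sequence alignment and per-homolog
    sets of 3D decoy models, the package extracts the conserved core (the
    alignment columns ungapped in all selected sequences), computes an
    all-vs-all core RMSD matrix over C3' atoms of core residues, clusters the
    pooled decoys by an iterative neighbor-count procedure with "1-of-6" and
    "half" stopping criteria, and selects the final model for the target
    sequence from the clustering output. Includes evaluation against a
    reference structure (heavy-atom RMSD, core RMSD, Interaction Network
    Fidelity), export of the distance matrix as a CLANS cluster map, and a
    seeded synthetic-fixture generator with planted cluster structure for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
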