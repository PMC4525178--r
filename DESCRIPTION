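Package: ligrecnet
Title: Ligand-Receptor Cell-to-Cell Communication Networks from Expression Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds draft maps of human cell-to-cell signalling from a
    gene-level expression atlas (TPM) and a curated set of ligand-receptor
    pairs. Classifies protein subcellular localization by tiered consensus
    rules (annotation first, prediction with transmembrane-helix constraints
    second), assembles a provenance-tracked ligand-receptor pair set from
    known-pair databases, protein-protein interaction evidence and manual
    curation, constructs thresholded cell-to-cell communication networks,
    extracts major-signalling pairs with lineage-level binomial enrichment
    statistics, and tests whether receptors predate their cognate ligands
    using phylostratigraphic ages with a length-bias-adjusted binomial null.
    A synthetic-data module generates all pipeline inputs with the assumed
    statistical structure for testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
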