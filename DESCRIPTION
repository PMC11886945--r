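Package: phytonet
Title: Feature-Based Molecular Networking and Scaffold Chemotaxonomy for
    Plant Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An untargeted LC-MS/MS metabolomics toolkit for plant natural
    products. Reads feature-linked MGF spectra and feature quantification
    tables, applies blank and replication filters, scores MS/MS spectra with
    a modified cosine similarity that pairs fragment peaks directly or offset
    by the precursor mass difference (neutral losses) under an exact
    one-to-one assignment, and builds feature-based molecular networks whose
    connected components group structurally related metabolites. Supports
    multi-tier dereplication against local spectral libraries (exact and
    analog matching) and repository-style metadata searches, plus delta-mass
    annotation propagation from confirmed compounds to network neighbours.
    A scaffold-mining workflow turns literature occurrence tables (such as
    Wikidata SPARQL output) into a curated genus-by-scaffold presence matrix
    via substructure inclusion/exclusion filtering, maps it onto a
    genus-level angiosperm phylogeny, and exports iTOL annotation datasets.
    Seeded synthetic-data generators with known ground truth exercise every
    stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    yaml,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
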