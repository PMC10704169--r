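Package: halolipid
Title: Halobacterial Lipidome Annotation, Molecular Networking and
    Chemotaxonomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for untargeted lipidomics of halophilic archaea:
    rule-based in-silico MS2 spectral libraries for archaeal ether
    lipids (archaeol cores, intact polar lipids, cardiolipins,
    menaquinones and bacterioruberin), tolerance-based feature
    annotation with blank and retention-time filtering, core-lipid
    chain accounting, feature-based molecular networking with the
    modified cosine score, and chemotaxonomic clustering compared
    against 16S rRNA neighbor-joining phylogenies. Includes a seeded
    synthetic-data generator emulating a multi-strain culture design
    so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    mclust,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
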