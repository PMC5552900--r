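Package: onenest
Title: Reconstruction of 1-Nested Phylogenetic Networks from Circular
    Split Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Combinatorics of uprooted 1-nested phylogenetic networks:
    split systems, compatibility and the incompatibility graph, circular
    orderings and circularity testing, the intersection and
    I-intersection closures of a split system, Buneman (median) graph
    construction with its block/gate/marguerite structure theory, and the
    provably optimal, unique reconstruction of a 1-nested network from a
    circular split system containing all trivial splits.  Includes a
    synthetic generator for random 1-nested networks and random circular
    split systems, plain-text and NEXUS SPLITS readers and writers, and
    GraphML/GML network import and export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
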