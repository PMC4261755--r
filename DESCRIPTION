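Package: cmapkit
Title: Contact-Map Comparison for Families of Rule-Based Biochemical Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parses rule-based biochemical models written in the BioNetGen
    language (BNGL) into compact contact maps (molecule nodes containing
    binding-site and state nodes, with edges for possible binding
    interactions), computes a graph-similarity metric over an
    adjacency-matrix abstraction of the map (shared node and edge counts,
    smaller-graph node and edge fractions, and their combined absolute
    score), sorts model families relative to the most complete member,
    computes pairwise shared- and difference-element sets and family-wide
    element membership, stabilizes force-directed layouts across a family by
    pinning shared elements to stored coordinates, and renders grayscale
    small-multiple panels with similarity and difference highlight overlays.
    Includes a seeded generator of synthetic BNGL model families with planted
    common cores and known edit sets for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, grDevices, igraph, jsonlite
Suggests: testthat (>= 3.0.0), xml2, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
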