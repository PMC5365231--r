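Package: kspathway
Title: Signaling-Pathway Reconstruction via k-Shortest Loopless Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs signaling pathways (and, in general, source-to-target
    sub-networks) in weighted directed interaction networks by computing the k
    best-scoring loopless paths from a set of source nodes (e.g. receptors) to a
    set of target nodes (e.g. transcription factors). The engine integrates
    Yen's k-shortest-loopless-paths algorithm with an A* heuristic driven by a
    reverse-traversal Dijkstra pass, supports unweighted, additive and
    probability (multiplicative) edge-weight models with an edge-length penalty,
    and assembles the ranked path table and the first-path-index-annotated
    sub-network. Includes a through-node shortest-path baseline, a synthetic
    network generator and a brute-force loopless-path enumerator used as a
    ground-truth oracle, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    optparse
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
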