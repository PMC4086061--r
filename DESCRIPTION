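Package: basenet
Title: Hydrogen-Bonded Base Interaction Networks in RNA 3D Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Annotates unbroken networks of hydrogen-bonded base-base
    interactions in RNA three-dimensional structures. Reads PDB-format
    coordinate files, detects base-base hydrogen bonds from heavy-atom
    donor/acceptor geometry, converts the bond list into a connection-table
    graph with signed atom-pair codes, enumerates the free-tree query shapes
    for base pairs through sextuples, searches structures for labeled tree
    patterns (with wildcard bases and per-edge bond-count constraints) by
    Ullmann subgraph matching with redundancy filtering, and reports the
    gained/lost/shared bonds between two similar structures. A synthetic
    fixture generator places idealized planar nucleobases so that prescribed
    bond networks hold by construction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
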