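Package: moltopo
Title: Topological 2D Molecular Graphs for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coloured mixed molecular graphs (covalent bonds, directed
    hydrogen-bond arcs, electrostatic and organometallic contacts) from
    Cartesian molecular-dynamics trajectories, identifies conformers by exact
    coloured-graph isomorphism, follows their interconversions through a graph
    of transitions, and analyses hydrogen-bonded ring topology via a Horton
    minimum cycle basis. Also implements the reverse mapping: a sequential-game,
    linear-reward-inaction reinforcement-learning generator that predicts a 3D
    structure from a hydrogen-inclusive molecular graph using VSEPR templates
    in place of any energy function, evaluated by superposition RMSD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tibble,
    rlang,
    ggplot2,
    igraph,
    pracma,
    yaml,
    stats,
    utils
Suggests:
    bio3d,
    xml2,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
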