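Package: antpath
Title: Ant Colony Optimization for Feasible Metabolic Pathway Synthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Synthesizes linear and branched metabolic pathways that relate a
    set of target compounds from available substrates, searching a
    set-of-compounds state space in which every partial solution is
    substrate-feasible by construction. Provides a pheromone-guided ant-colony
    search with pathway cleaning and a four-component cost (length, unique
    reactions, productive reactions, target connectivity), exhaustive
    breadth-first and depth-limited depth-first baselines over the same state
    space, pathway-quality metrics (connectivity, branching factor,
    precision/recall/accuracy against reference pathways), readers and writers
    for a KEGG-style reaction table format, and a synthetic reaction-network
    generator with planted pathways for benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
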