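Package: netmodmap
Title: Integrative Mapping of Topological, Functional and Disease Modules
    in Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects topological modules in human protein-protein interaction
    networks with pluggable community detectors (greedy modularity
    agglomeration, Markov clustering, seeded random walk with restart), calls
    functional, pathway, disease and protein-complex modules on them using
    hypergeometric over-representation tests with Benjamini-Hochberg
    correction and coverage/counting rules, classifies modules as non-trivial
    or significant by cross-layer overlap, and evaluates detectors by Newman
    modularity and layer mapping frequencies. Includes a seeded
    planted-partition generator that emits synthetic interaction tables and
    annotation layers in the package's file formats, and a command-line
    pipeline with staged subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
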