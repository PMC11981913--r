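Package: neurodecomp
Title: Graph Decomposition, Automated Proofreading and Connectivity
    Analysis for Neuron Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes neuron surface meshes and synapse tables into
    soma-rooted graphs of non-branching segments annotated with widths,
    synapses and dendritic spines.  Provides heuristic graph filters that
    locate and strip segmentation merge errors (axon-on-axon,
    axon-on-dendrite, soma bridges, double-backs, width jumps), spine
    head/neck segmentation, excitatory/inhibitory classification from
    spine and synapse densities, axon-dendrite proximity detection with
    conversion rates and skeletal-walk distances, and a triad-motif census
    against degree-preserving, proximity-constrained and uniform null
    models.  Ships a synthetic-neuron generator with per-face and
    per-synapse ground truth so the whole pipeline is testable without
    external volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
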