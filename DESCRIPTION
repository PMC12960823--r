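Package: bdpath
Title: Elastic-Network Brownian Dynamics Sampling of Protein Conformational
    Transition Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained simulation of conformational transitions between
    two experimentally determined protein states. Each residue is reduced to
    its C-alpha bead and embedded in an elastic network with a distance cutoff
    and optional rigid blocks; overdamped Brownian dynamics is biased toward
    the target state by importance sampling on a rotation-invariant pairwise
    distance progress variable, with periodic accept/reject checkpoints.
    Includes ensemble principal component analysis with Kabsch superposition,
    transition metrics (RMSD, collectivity degree, consecutive C-alpha
    stereochemistry, subspace overlap and RMSIP, three-point angles),
    multi-model PDB trajectory input/output, and synthetic two-state fixture
    generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
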