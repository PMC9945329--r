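Package: kinstab
Title: Protein Kinetic Stability from Contact Topology, Coarse-Grained
    Folding Simulation, and Denaturation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying and engineering protein kinetic stability.
    Computes residue contact maps from PDB structures (plain distance-cutoff
    and shadow-occlusion variants), the topology metrics long-range order
    (LRO) and absolute contact order (ACO), and log-linear predictions of
    midpoint unfolding rate constants from those metrics. Builds and
    simulates coarse-grained C-alpha structure-based (Go-type) folding
    models with a Langevin integrator, locates folding temperatures,
    extracts free-energy profiles F(Q) with Boltzmann reweighting to equal
    basin depths, and measures unfolding barrier heights. Fits experimental
    kinetic traces, chevron plots, and equilibrium denaturation curves with
    the two-state linear extrapolation model, and derives m-values,
    beta-Tanford values, unfolding free energies, transition midpoints, and
    half-lives. Includes homolog core-swap design comparison with
    interquartile-range outlier screening and deterministic synthetic-data
    generators for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
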