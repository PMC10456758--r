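Package: swarmentropy
Title: Entropy by Neighbor Distance for 2-D Collective Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies spatial order in two-dimensional collective systems
    (boid simulations, active colloids, robotic swarms) through the Shannon
    entropy of the neighbor-distance distribution (H_NDist) and its
    bin-width-normalized variant. Neighbors are defined either topologically,
    via Voronoi tessellation under open or periodic boundaries, or metrically,
    via a fixed interaction radius. Includes a Vicsek-style boid simulator with
    cohesion, separation and alignment rules, the average-velocity order
    parameter, noise and bin-size sweep drivers, synthetic pattern generators
    (lattices, gas, Gaussian clusters, letter-masked packings) and a trajectory
    CSV dialect for tracked coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deldir,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
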