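Package: ptwschool
Title: Persistent Turning Walker Models of Fish Schooling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for stochastic models of
    collective fish motion in which each individual swims at constant
    speed while its angular velocity follows an Ornstein-Uhlenbeck
    process relaxing toward a stimulus-dependent target turning speed.
    The target combines wall avoidance in a circular tank with
    attraction and alignment to neighbours defined by topological
    (first-shell Voronoi or k-nearest-neighbour) interaction networks.
    Includes an agent-based simulator, reconstruction of headings and
    angular velocities from sampled trajectories, parameter estimation
    by nonlinear least squares on the Ito-discretised process, residual
    diagnostics, collective order statistics (polarization,
    inter-individual distance), and a generator of experiment-like
    synthetic trajectory datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
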