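Package: progmapper
Title: Mapper-Based Progression Analysis of Longitudinal Clinical Scores
Version: 0.1.0
Authors@R:
    person("Maintainer", "Progmapper", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Topological progression analysis for longitudinal clinical
    cohorts. Builds a mapper graph over a patient-visit point cloud using a
    two-dimensional coordinate-projection filter, estimates per-medication
    Markov chains on the overlapping mapper clusters from consecutive-year
    visit pairs, and derives expected one-year score growth, counterfactual
    (un-medicated) medication-effect comparisons, and a kernel-weighted
    nearest-neighbour prediction of the next year's motor score with
    leave-one-out evaluation. Includes Vietoris-Rips persistent homology
    (dimensions 0 and 1) with bottleneck and Wasserstein diagram distances
    for topology-preserving feature elimination, and a synthetic longitudinal
    cohort generator for end-to-end testing without access to gated clinical
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
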