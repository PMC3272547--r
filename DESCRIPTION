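Package: crestswarm
Title: Agent-Based Simulation and Trajectory Statistics for Collective
    Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates collective migration of mesenchymal cell
    populations (such as the neural crest) as constant-speed
    self-propelled particles coupling short-range contact-inhibition
    repulsion with longer-range mutual chemoattraction via a secreted
    attractant field, in corridor, confrontation and unbounded arenas.
    Provides the companion trajectory-statistics toolkit for any 2-D
    cell-track table: Delaunay-triangulation dispersion, coattraction
    vectors with circular dispersion, Rayleigh and V tests, chemotaxis
    index, directional persistence, angular deviation from the group
    path, and proximal/distal directional-bias analysis. Includes
    deterministic synthetic-track and point-cloud generators with
    closed-form directional statistics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    deldir,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
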