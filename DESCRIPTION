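Package: extrudesim
Title: Three-Dimensional Multi-Phase-Field Simulation of Cell Extrusion in Active Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a confluent monolayer of deformable, self-propelled cells on a
    rigid substrate with a three-dimensional multi-phase-field model, and analyses the
    resulting trajectories: detection of cell extrusion events, nematic half-integer
    defect detection and tracking in the basal orientation field, neighbor graphs and
    hexatic (fivefold/sevenfold) disclinations, Lewis-law diagnostics, coarse-grained
    three-dimensional mechanical stress fields, defect-frame averaged stress maps, and
    a Poisson point-process null model with a two-sample Kolmogorov-Smirnov test for
    the correlation between extrusions and topological defects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
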