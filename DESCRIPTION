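Package: porewatch
Title: Permeation and Occupancy Analysis for Shell-Protein Channel Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how solutes and monatomic ions
    permeate the central pore of bacterial-microcompartment shell-protein
    hexamers. Provides trajectory and structure readers (PDB, GRO, DCD,
    multi-frame XYZ), per-molecule center-of-geometry tracks with periodic
    reassembly, Kabsch rigid-body superposition onto a crystallographic
    reference defining a pore-axis coordinate system, cylindrical axial
    occupancy profiles with cross-replica standard errors, bidirectional
    permeation-event detection and rate estimation, 3D spatial distribution
    functions with bulk-enrichment thresholding, a Brownian-dynamics
    generator of channel-translocation trajectories with logged ground-truth
    crossings, and an enzyme-kinetics module for initial-velocity analysis
    of compartment permeability assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
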