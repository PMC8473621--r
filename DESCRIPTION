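Package: osteoseed
Title: Scaffold Cell-Seeding Simulation and Bone-Ingrowth Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled simulation of bone-marrow filling and bone mesenchymal
    stem cell (BMSC) attachment onto a 3D-printed titanium osteochondral
    scaffold, together with the X-ray based bone-ingrowth quantification that
    validates it. Includes a parametric truncated-cone lattice generator with
    voxel morphometrics (porosity, surface area), a power-law non-Newtonian
    rheology model for bone marrow, a two-phase (marrow/air) volume-of-fluid
    flow solver on an axisymmetric section of the defect, Lagrangian particle
    tracking of cells with a Weber-number impingement model (stick, rebound,
    spread), grid-wise bone-fraction statistics with 4-/8-connected
    bone-scaffold contact scoring on radiographs, and a synthetic radiograph
    generator providing ground-truthed fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
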