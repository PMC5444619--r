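Package: atheroabm
Title: Agent-Based Simulation of Leukocyte Transendothelial Migration and
    Atherosclerotic Plaque Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multiscale agent-based simulator of early atherogenesis in a
    left-anterior-descending-like coronary artery. A cylindrical artery is
    voxelized into 100 micrometre patches; cytokines (TNF-alpha, IL-1beta,
    IL-10) and low-density lipoprotein diffuse through the wall by Fick's
    law; leukocytes adhere to and transmigrate across the endothelium with
    probabilities driven by wall shear stress and endothelial cytokine
    exposure; cells inside the wall follow chemotactic gradients,
    differentiate into macrophages and foam cells, age and die; and the
    artery remodels according to the Glagov phenomenon (outward growth while
    plaque is below 40% of lumen area, mixed inward/outward beyond it).
    Wall shear stress comes from a pluggable backend: a Poiseuille
    effective-radius estimator, a built-in steady axisymmetric
    stream-function/vorticity solver that captures post-stenotic low-shear
    zones, or an imported per-patch field. Includes experiment drivers for
    cardiac-cycle timescale studies, accelerated stenosis sweeps,
    perturbation stability checks, and cell-type knockouts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
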