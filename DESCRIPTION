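Package: ecmabm
Title: Agent-Based Simulation of Cells in a Remodelable Extracellular Matrix
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mesoscale agent-based modeling framework coupling off-lattice,
    center-based cell agents to a voxelized extracellular matrix (ECM). Each
    ECM element carries a fiber orientation, an anisotropy (fiber-fiber
    alignment) and a density; cells read these fields through contact
    guidance and density-dependent migration speed, and write them back
    through fiber reorientation, anisotropy growth and density remodeling.
    The package includes a multi-substrate implicit diffusion-decay solver,
    a Hill-response rules engine mapping local signals to cell behaviors,
    seeded scenario builders (invasive cellular front, fibrosis, basement
    membrane degradation, leader-follower collective migration and
    proof-of-concept fields), and quantification utilities (front-advance
    histogram metric, wound-enclosure classifier, replicate summaries).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
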