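Package: icmDynamics
Title: Cell Sorting, Matrix Dynamics and Geometric Scaling in the Blastocyst Inner Cell Mass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying epiblast and primitive endoderm (PrE) patterning
    in the mammalian blastocyst inner cell mass (ICM). Provides a 3D Poissonian
    cellular Potts simulator with cell growth, division and extracellular-matrix
    secretion by PrE cells; statistics over fate-labelled 3D cell trajectories
    (radial dynamics, sorting scores, displacement maps, first-passage
    probabilities, fate-switch detection); image-derived quantification
    operators (Young-Laplace interfacial tension, polarization index, intensity
    profiles, membrane curvature, boundary-orientation binning, shape
    descriptors, depth-corrected k-means fate classification, colocalization);
    a spherical-cap geometric model predicting whether a fixed PrE fraction can
    tile the ICM-cavity interface as a monolayer across embryo sizes and
    species; and seeded synthetic-data generators for every input the analysis
    stages consume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
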