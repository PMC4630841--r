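Package: morphotraj
Title: Ontogenetic Trajectory Analysis for 3D Landmark Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric-morphometric inference chain for comparing ontogenetic
    (allometric) trajectories among groups of 3D landmark configurations:
    generalized Procrustes superimposition with object symmetry, thin-plate-spline
    estimation of missing landmarks, covariance-matrix principal component
    morphospaces, multivariate regression of shape on log centroid size with
    permutation tests and trajectory-angle comparison, group-mean Procrustes
    distance permutation tests, rank tests, and a squared-change parsimony
    permutation test of phylogenetic signal on a phylogeny. Includes a synthetic
    landmark-data generator with known ground truth that emulates a multi-species,
    two-age-class cranial and mandibular study design, plus TPS/CSV file I/O and a
    config-driven end-to-end runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
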