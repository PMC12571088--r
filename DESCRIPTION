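Package: toothspace
Title: Landmark-Based Tooth Morphospace Analysis and Extinction Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tooth-crown shape from 2D landmark configurations
    (TPS files with fixed landmarks and sliding semilandmark curves),
    superimposes them by generalized Procrustes analysis with a
    bending-energy sliding criterion, ordinates species mean shapes, and
    simulates threat-ordered extinction scenarios against Monte Carlo
    random-extinction null models, tracking convex-hull occupation,
    centroid displacement and average pairwise Procrustes distance (APPD).
    Includes residual-randomization permutation ANOVA and pairwise shape
    contrasts, a multivariate Blomberg-type phylogenetic signal statistic,
    compositional (centered log-ratio) diet analyses with ordinated dietary
    niche breadth and multivariate dispersion homogeneity, and a synthetic
    data generator emulating tooth-like landmark data with among-species
    Brownian structure, ordered threat statuses with tunable morphology
    selectivity, Dirichlet diet compositions and a pure-birth phylogeny.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    phytools,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
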