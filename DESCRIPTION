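Package: orthoflow
Title: Digital Planning, Simulation and Evaluation for Orthognathic Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale geometry toolkit for the fully digital orthognathic
    surgery workflow: fusion of optical dentition scans with CT-derived
    skeletal models by trimmed, k-d-tree-accelerated iterative closest point
    (ICP) registration refined with rigid coherent point drift (CPD);
    reproduction of the natural head position from a single facial photograph
    by POSIT 2D-3D pose estimation; plane-cut virtual osteotomy and rigid
    surgical planning of bone segments (axis translations and
    center/target/goal rotations); and 3D landmark-based accuracy evaluation
    reporting per-landmark linear (x/y/z/RMS) and occlusal-plane angular
    (pitch/roll/yaw) discrepancies with summary statistics, ANOVA, Pearson
    correlation and Kolmogorov-Smirnov normality checks. Includes seeded
    synthetic skull phantoms with known ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
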