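Package: megpool
Title: Multi-Subject MEG Source Estimation by Source-Space Averaging and
    Minimum Wasserstein Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how pooling magnetoencephalography (MEG) data
    across subjects improves source localization. Implements the eLORETA
    weighted minimum-norm inverse with SNR-based regularization and
    source-space averaging, minimum Wasserstein estimates (MWE) that couple
    per-subject sparse inverse problems through an unbalanced
    entropic-optimal-transport barycenter, and the modified binary searches
    that calibrate the MWE sparsity and coupling hyperparameters. A synthetic
    multi-subject retinotopy generator provides template icosphere source
    spaces, analytic spherical-conductor (Sarvas) leadfields with
    inter-subject jitter, and evoked responses with controlled amplitude SNR,
    so that peak-to-target geodesic distance metrics (with Winsorizing and
    wrong-hemisphere outlier rules) can be evaluated end to end with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
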