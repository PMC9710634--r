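Package: fedpca
Title: Federated Principal Component Analysis for Horizontally Partitioned Data
Version: 0.1.0
Authors@R:
    person("Federated", "PCA Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Simulates federated principal component analysis over
    horizontally partitioned (samples-split-across-sites) biomedical data
    in a star topology. Implements one exact covariance-aggregation method
    (P-COV), two approximate subspace-aggregation methods (AP-COV,
    AP-STACK), a QR-merge method (QR-PCA) and federated subspace iteration
    (SUB-IT), together with federated centering and scaling via summary
    statistics, per-message communication accounting with closed-form cost
    predictions, accuracy metrics against the centralized eigendecomposition
    (per-eigenvector angles, reconstruction-error ratios), a synthetic
    generator for low-rank-plus-noise expression-like matrices with skewed
    non-iid site assignments and site-specific batch effects, and a
    privacy-aware visualization that shares only Gaussian-resampled
    projections instead of exact ones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
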