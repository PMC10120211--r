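Package: piicm
Title: Permutation-Invariant Multi-Output Gaussian Processes for Drug
    Combination Dose-Response Prediction
Version: 0.1.0
Authors@R:
    person("piicm", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage probabilistic modelling of in-vitro drug combination
    screens. Stage one fits each (cell line, drug pair) experiment with a
    Bayesian dose-response model: log-logistic monotherapy curves, a Bliss
    independence non-interaction surface, and a latent Gaussian-process
    interaction term pushed through a bounding transform. Stage two models
    the latent fields of all experiments jointly with a permutation-invariant
    intrinsic coregionalization model (ICM), so that dose-response surfaces
    of held-out experiments can be predicted and reconstructed. Inference
    exploits the Kronecker structure of the covariance via structured
    matrix-vector products, masked preconditioned conjugate gradients, and an
    eigenvalue-based approximation of the log-determinant. Includes synthetic
    screen generators so the whole pipeline is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
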