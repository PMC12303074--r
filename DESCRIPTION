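Package: patjrec
Title: Joint Reconstruction of Initial Pressure and Speed of Sound in
    Photoacoustic Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based inversion framework for two-dimensional photoacoustic
    tomography (PAT) that reconstructs several initial pressure distributions
    together with a shared heterogeneous speed-of-sound map from simulated
    boundary sensor data.  Acoustic propagation is modelled with a k-space
    pseudo-spectral time-domain solver (split-field perfectly matched layer,
    k-space corrected spectral derivatives); gradients of the penalised
    least-squares objective are obtained with the adjoint-state method;
    Ornstein-Uhlenbeck Gaussian priors regularise each unknown field; the
    minimisation uses bound-constrained limited-memory BFGS with projected
    backtracking line search and coarse-to-fine multigrid continuation.
    Synthetic phantom generators (circular-inclusion targets and
    tissue-mimicking optical targets lit through a diffusion-approximation
    light model) provide the simulated study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
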