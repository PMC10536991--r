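Package: tbtrain
Title: Trainable Spline-Parameterized Self-Consistent-Charge Tight Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and exports self-consistent-charge tight-binding
    (SCC-DFTB) models whose Hamiltonian, overlap and repulsive interactions are
    regularized splines of interatomic distance. Parameters are trained
    end-to-end against reference energies, dipoles and atomic charges with a
    loop-inverted schedule that freezes charge fluctuations between periodic
    self-consistent-field refreshes, fits the repulsive potential and linear
    reference energy by convex optimization, and enforces curvature-sign and
    third-derivative smoothing penalties on all electronic channels. Trained
    models are written in the Slater-Koster file (SKF) format. A synthetic-data
    generator provides an analytic Slater-type-orbital ground truth for
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    splines,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
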