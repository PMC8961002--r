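Package: sandix
Title: Soma and Neurite Compartment Models with Water Exchange for
    Gray-Matter Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Powder-averaged compartment models of the gray-matter diffusion
    MRI signal with and without neurite water exchange (SANDI, SMEX, SANDIX,
    eSANDIX). Implements a generalized Karger two-compartment exchange engine
    for arbitrary piecewise-linear q(t) encodings, its narrow-pulse closed
    form and large-b expansion, the exchange-versus-structure diffusion-time
    signature, Gaussian-phase sphere diffusivities, multi-start nonlinear
    least-squares fitting with variable projection over the linear signal
    fractions, BIC model comparison, MR soma-radius and permeability
    analysis, Rician noise synthesis and bias correction, and a Monte Carlo
    simulator of restricted diffusion in parametric geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
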