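Package: tectrepair
Title: Brain Wound Closure Mechanics and Trajectory Analysis for the Larval Zebrafish Optic Tectum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying mechanical wound closure in the
    larval zebrafish optic tectum. Implements a viscoelastic damped-oscillator
    model of wound-closure kinetics with nonlinear least-squares fitting,
    trajectory statistics for tracked cell nuclei (mean-squared displacement
    with power-law exponent estimation, straightness, rostrocaudal
    linearisation, displacement-field convergence with polar normalisation,
    and the discrete Frechet distance with a randomised null), wound
    morphometry (outline-stack injury volumes, the repair index, nuclear
    packing density, laser-ablation mask metrics), a 2D multi-agent tissue
    simulator with microglial elastic traction, and seeded synthetic-data
    generators emulating the structure of in vivo tracking and imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    knitr
Config/testthat/edition: 3
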