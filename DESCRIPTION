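Package: gapdyn
Title: Dynamical Modules, Phase-Space Analysis, and Fitting of Gap Gene
    Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and dynamical analysis of connectionist gene
    circuit models of the Drosophila gap gene network. Implements the
    hybrid interphase/mitosis/division model for rows of diffusion-less
    nuclei driven by maternal morphogen gradients, node-sensitivity
    screening for the discovery of dynamical modules, extraction and
    simulation of three-gene AC/DC subcircuits, instantaneous (frozen-time)
    phase portraits with Newton-Raphson steady-state search and
    eigenvalue-based attractor classification, phase diagrams of dynamical
    regimes (multistability, damped oscillations, limit cycles) over
    maternal inputs and regulatory weights, and a weighted root-mean-square
    objective with a desk-scale multi-start optimizer for parameter
    recovery on synthetic data. A synthetic-data module generates maternal
    gradients, ground-truth circuits, and noisy expression datasets so the
    full analysis pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
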