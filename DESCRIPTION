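Package: loopmech
Title: Base-Pair-Step Mechanics and Thermodynamics of Protein-Mediated DNA Loops
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for modelling short repressor-mediated DNA loops at the
    rigid base-pair-step level. Builds and inverts base-pair frames from the
    six step parameters (tilt, roll, twist, shift, slide, rise), scores
    configurations with a harmonic elastic potential calibrated to the
    persistence length and torsional rigidity of mixed-sequence DNA,
    energy-optimizes loops between fixed protein-bound end frames in eight
    orientation/topology states (with frozen architectural-protein
    footprints introduced by ramping, one-base-pair chain growth and steric
    screening), and converts optimized ensembles into looping J-factors and
    state fractions. A companion thermodynamic module implements the
    repression-level algebra of lac-operon reporter assays and fits
    helical-phasing models of repression versus operator spacing by
    nonlinear least squares. A synthetic-data module generates reporter-style
    datasets, idealized TALE and HMGB (Nhp6A) footprints and toy repressor
    boundaries so that the full pipeline runs without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
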