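Package: ionselect
Title: Free-Energy and Selectivity Analysis for Ion-Channel Permeation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators and synthetic-data generators for locating and
    quantifying cation selectivity in narrow ion-channel pores. Implements
    potential-of-mean-force estimation by direct Boltzmann inversion and by the
    weighted histogram analysis method (WHAM) over harmonic umbrella windows,
    block-based error analysis and convergence series; the Bennett acceptance
    ratio (BAR) estimator with single- and double-occupancy alchemical
    thermodynamic cycles and error propagation; trajectory-frame geometry
    analysis (radial distribution functions, first-shell coordination profiles,
    ion occupancy classification at carboxylate sites); and electrophysiology
    analysis (leak subtraction, reversal potentials, Goldman-Hodgkin-Katz
    permeability ratios, four-parameter Hill pH50 fits). A bundled overdamped
    Langevin simulator and work/frame/recording generators provide inputs with
    known ground truth for validation, in place of cluster-scale molecular
    dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    graphics,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
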