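Package: hopdyn
Title: Trajectory Surface Hopping with Arbitrary Electronic Couplings on Model Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fewest-switches trajectory surface hopping in the diagonal
    representation, i.e. on the eigenstates of a total electronic Hamiltonian
    that may contain spin-orbit and laser-dipole couplings on top of the
    spin-free states. Provides analytical linear-vibronic-coupling model
    potentials as electronic-structure surrogates, a three-step electronic
    propagator with local diabatization and overlap-based phase tracking,
    kinetic-energy adjustment with frustrated-hop handling, energy-based
    decoherence, Wigner-distribution initial-condition sampling, stochastic
    initial-state selection, an ensemble driver, and ensemble analysis
    (population protocols, first-order kinetic-model fitting with bootstrap
    errors, hop-geometry extraction, internal coordinates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
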