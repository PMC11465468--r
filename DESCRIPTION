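Package: cooxr
Title: Constraint-Based Orbital-Optimized Excited States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-consistent-field calculation of targeted electronic excited
    states by constrained density-functional / Hartree-Fock theory. Implements
    the constraint-based orbital-optimized excitation (COOX) scheme, in which
    the constraint potential is assembled from the occupied-occupied and
    virtual-virtual blocks of a linear-response (Tamm-Dancoff) excited-state
    difference density, together with its scaled-constraint variant for
    degenerate frontier orbitals and the x-cDFT and t-cDFT comparison schemes.
    Includes a compiled McMurchie-Davidson Gaussian-integral backend with a
    built-in minimal basis, Fermi-smearing fractional occupations, a nested
    macro/micro constrained SCF solver, excitation diagnostics (excited-electron
    count, single/double character), excited-state nuclear gradients with a
    geometry optimizer, and XYZ/cube/JSON input-output plus a small command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
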