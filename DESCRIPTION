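Package: hyscoreR
Title: Simulation and Analysis of HYSCORE Spectra of Low-Spin Ferric Heme
    Centers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative interpretation of pulse-EPR
    (HYSCORE/ESEEM) data from S = 1/2 metal centers, with an emphasis on
    low-spin ferric heme proteins. Implements Taylor crystal-field analysis
    of rhombic g-values, orientation-selective spin-Hamiltonian simulation
    of nuclear transition frequencies and four-pulse HYSCORE time traces
    for 1H, 2H, 14N and 15N nuclei (exact nuclear sub-Hamiltonian
    diagonalization including the nuclear quadrupole interaction), the
    standard 2D processing chain (polynomial baseline, apodization,
    zero-filling, 2D FFT magnitude), Dikanov squared-frequency ridge
    analysis, and point-dipole inversion of anisotropic hyperfine couplings
    to metal-nucleus distances and placements in the g-frame. Includes a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
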