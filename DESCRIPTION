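Package: lfnmr
Title: Simulation and Detection-Limit Analysis for Low-Field Benchtop 1H NMR Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing metabolite detectability on low-field (80 MHz)
    benchtop 1H NMR spectrometers without spectrometer access. Includes a
    quantum-mechanical spin-system simulator with full strong-coupling
    treatment (Hamiltonian diagonalization, Lorentzian rendering), a synthetic
    multi-scan acquisition model with pulse-sequence profiles and residual
    water, reference-peak (TSP) alignment and scaling, three signal-to-noise
    ratio conventions with limit-of-detection and limit-of-quantification
    threshold analysis, cumulative-intensity metabolite bounds, simulation-based
    template fitting with bounded nonlinear least squares, and signal-ratio and
    power-law scan-scaling analyses. Ships spin-system parameters for glucose
    (alpha/beta anomers), lactate, citrate and TSP.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
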