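Package: iondose
Title: Desk-Scale Condensed-History Monte Carlo Dose Engine for Therapeutic Ion Beams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates therapeutic proton and light-ion (helium, carbon,
    oxygen) beams in voxelized phantoms with a condensed-history Monte
    Carlo. Electronic stopping power follows the Bethe-Bloch formalism
    with density, shell, effective-charge, Barkas, Bloch and Mott
    corrections; energy-loss straggling uses a Gaussian (Bohr) model,
    multiple Coulomb scattering the Highland formula, and nuclear
    attenuation a cross-section driven removal with a forward
    fragment-tail surrogate. Includes Hounsfield-unit stoichiometric
    material calibration, mixed-field linear-quadratic RBE-weighted dose
    with spread-out Bragg peak optimization, depth-dose comparison
    metrics (Bragg-peak position, dose-weighted dose difference, weighted
    chi-square, DVH), and beta-plus-emitter / PET range-verification
    scoring with ring-detector coincidence simulation and sinogram
    binning.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
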