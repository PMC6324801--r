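Package: linacmc
Title: Monte Carlo Modelling and Dosimetric Analysis of Flattened and
    Flattening-Filter-Free Linac Photon Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale Monte Carlo model of a medical linear accelerator
    treatment head in flattened (6 MV) and flattening-filter-free (FFF, 7 MV)
    mode, together with the complete dosimetric analysis pipeline used to
    characterise such beams.  The transport engine samples bremsstrahlung
    production in the target, collimation, flattening-filter attenuation,
    contaminant-electron production in head and air, and coupled
    photon-electron transport in a voxelised water phantom with batch-based
    statistical uncertainties.  Analysis tools cover percentage depth-dose
    and lateral-profile metrics (penumbra, dosimetric field size, unflatness,
    slope, peak position, symmetry), shoulder-point renormalisation of FFF
    profiles, photon and electron fluence spectra, electron-contamination
    separation via paired electron-kill runs, off-axis spectral scans,
    phase-space files with recycling, and a two-stage commissioning procedure
    that tunes the primary electron source against reference water-tank scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    signal,
    yaml,
    jsonlite,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
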