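Package: photonsar
Title: Optical Reflectance, Wireless Power and SAR Dosimetry Modelling for
    Implantable Photonic Neurostimulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale modelling pipeline for implantable photonic
    neurostimulation devices. Couples wavelength-dependent pulsatile tissue
    reflectance in a layered brain phantom with an embedded vessel (modified
    Beer-Lambert analytics and 2D Monte Carlo radiative transport over the
    hemoglobin absorption spectrum), resonant inductive wireless-power-transfer
    link design (LC resonance, S11 return loss), and quasi-static
    electromagnetic dosimetry on a voxel head phantom (Biot-Savart coil
    fields, pointwise specific absorption rate, and 10 g mass-averaged SAR
    with spherical, hemispherical and air-excluding adaptive kernels) against
    the 2 W/kg localized-exposure limit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
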