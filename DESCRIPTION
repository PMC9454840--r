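Package: stimwell
Title: Electric-Field Dosimetry for Plate-Electrode Cell-Culture Stimulation Chambers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Characterizes the electric field delivered to cells in a
    12-well plate-electrode AC stimulation chamber. Solves the 2D
    electrostatic Laplace equation in the liquid cross-section with a
    piecewise-linear finite-element method, extracts centerline field
    profiles, homogeneity metrics and electrode currents by consistent
    boundary-flux integration, models biphasic rectangular pulse
    waveforms and per-well dose metrics (duty cycle, average power,
    deposited energy, adiabatic temperature-rise bound), validates
    predicted currents against shunt-resistor measurements, and
    generates synthetic current traces and perturbed geometries for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
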