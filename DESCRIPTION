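Package: xfetring
Title: Digital Twin of a Full-Ring Benchtop X-Ray Fluorescence Emission
    Tomography System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward photon-transport simulation and list-mode analysis chain
    for a benchtop X-ray fluorescence emission tomography (XFET) scanner built
    around a hexagonal ring of 24 pixelated CdTe spectrometers and a 96-pinhole
    compound-eye collimation aperture.  Provides embedded atomic-physics tables
    (K emission lines, K edges, fluorescence yields, mass attenuation), an
    analytic polychromatic source-spectrum model, construction and ray-tracing
    of the multi-pinhole system geometry, analytic phantoms for the two
    in-system gadolinium and lanthanum studies, a seeded Monte-Carlo list-mode
    event simulator (pencil-beam excitation, pinhole transport, Klein-Nishina
    Compton background, detector response and charge sharing), the detector-side
    processing chain (per-pixel two-point energy calibration, 3x3 charge-sharing
    discrimination), pinhole-view merging and windowed net-XRF image formation,
    contrast-to-noise / Rose-criterion detectability and multi-element
    quantification metrics, and kerma-approximation dosimetry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff
Config/testthat/edition: 3
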