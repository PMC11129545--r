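# xfetring

A digital twin of a benchtop **X-ray fluorescence emission tomography
(XFET)** system built around a full hexagonal ring of 24 pixelated CdTe
spectrometers (80 × 80 pixels, 250 µm pitch, opposite panels 82 mm apart) and
a 96-pinhole **compound-eye** tungsten collimator: each 1-mm knife-edge
pinhole views the pencil-beam-illuminated line through the object onto its
own non-overlapping 1 cm × 1 cm subdetector region at 1:2 minification.

The package is for instrumentation and image-science work on benchtop XFET:
it simulates and processes complete acquisitions of a small-animal-sized
phantom containing gadolinium and lanthanum solutions, from source spectrum
to quantitative elemental images.

## What it computes

For a beam position x and an element with K-edge energy E_K, the expected
K-emission density along the beam is

    dN(y) = Φ Σ_{E ≥ E_K} w(E) T(E, y) · c τ_el(E) · (J−1)/J · ω_K dy

(Φ beam photons, w the spectrum, T the transmission to depth y, c the element
concentration, τ_el the photoelectric mass coefficient, J the K jump factor,
ω_K the fluorescence yield). Emitted photons are transported through the
96-pinhole aperture (solid-angle acceptance A cosθ / 4πd²), attenuated along
their exit paths, and detected with the measured energy response (FWHM 0.5
keV at 35 keV); single-scatter Compton background is generated from the
Klein–Nishina distribution by forced detection. Images are formed exactly as
the instrument's processing chain defines: charge-sharing discrimination in
3 × 3 pixel neighborhoods per readout frame, merging of the 96 views by ray
back-projection onto the beam line, column collapse, and per-row net-XRF
extraction in a 3 keV window around the Kα peak (42.75 keV for Gd, 33.30 for
La) over a linear background fitted to flanking sidebands — giving the
20 × 37 voxel (1 mm × 0.5 mm) elemental image. Quantification uses

    CNR = (C_tube − C_bkg) / σ_bkg ,   SNR = net / σ_Compton per voxel

with 5 × 5 voxel ROIs and the Rose criterion (CNR ≥ 3 and SNR ≥ 5).

## Worked example

Simulate the two-element phantom study (Gd:La 3:6, 3:3, 6:3 mg/mL tubes plus
water, 19-mm acrylic body), process it, and quantify the concentration
ratios:

```r
library(xfetring)

geometry <- xfet_geometry()          # 24 modules, 96 pinholes
spectrum <- source_spectrum()        # 90 kVp Mo anode, 254 um Be window
phantom  <- phantom_study_II()
plan     <- make_scan_plan(37, 0.5, dwell = 10)

scan <- simulate_scan(phantom, plan, geometry, spectrum,
                      flux = 1e8, seed = 301, compton = FALSE)
gd <- xfet_image_from_scan(scan, geometry, plan, "Gd")
la <- xfet_image_from_scan(scan, geometry, plan, "La")
print(gd)
#> <xfet_image> Gd : 20 x 37 voxels, 1 x 0.5 mm; total net 9084

rois <- lapply(2:4, function(i)
  roi_at(gd, phantom$tubes$x[i], phantom$tubes$y[i]))
observed <- concentration_ratio(gd, la, rois)
round(observed, 3)
#> [1] 0.254 0.510 0.987
round(mean(c(0.5, 1, 2) / observed), 3)
#> [1] 1.984
```

The observed Gd:La ratios per tube sit below the true 0.5 / 1 / 2 by a
constant factor (~2 in this model): fewer beam photons are available above
the Gd K edge (50.2 keV) than above the La edge (38.9 keV), and the La
photoelectric cross section just above its own edge is ~1.4× the Gd one —
so per mg/mL, La fluoresces more efficiently. Geometric sensitivity and dose:

```r
geometric_sensitivity(geometry, c(0, 0, 0), n_samples = 1e6, seed = 1)$sensitivity
#> [1] 0.007204   # 0.72% of isotropic emissions from the FOV center accepted
dose_report(0.88, 10, 37)
#> <dose_report> 0.88 cGy/min x 10 min = 8.8 cGy/position; 37 positions -> 325.6 cGy (~326 cGy)
```

A thin command-line front end ships in `inst/cli/xfet.R`
(`simulate`, `image`, `quantify`, `dose`, `dose-mc` subcommands).

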