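---
title: "Modeling a full-ring compound-eye XFET system: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a full-ring compound-eye XFET system: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xfetring)
```

## The imaging problem

X-ray fluorescence emission tomography (XFET) images the spatial distribution
of high-Z contrast elements (gadolinium, lanthanum, gold, ...) in a small
object by irradiating it with a pencil beam of X-rays and detecting the
characteristic K photons that excited atoms emit. `xfetring` is a digital twin
of a benchtop full-ring implementation: six detector panels in a hexagonal
ring (24 CdTe spectrometer modules of 80 x 80 pixels at 250 um pitch, opposite
panels 82 mm apart), coupled to a 96-pinhole "compound-eye" tungsten
collimator in which each 1-mm knife-edge pinhole projects the illuminated beam
line onto its own non-overlapping 1 cm x 1 cm subdetector region with a 1:2
minification. Because every view images the same one-dimensional beam segment,
an elemental image can be formed line-by-line from windowed net counts without
tomographic reconstruction.

The package contains the complete chain: embedded atomic physics, system
geometry and ray tracing, analytic phantoms, a seeded list-mode Monte-Carlo
forward simulator, the detector-side processing (per-pixel energy calibration
and charge-sharing discrimination), view merging and net-XRF image formation,
detectability and quantification metrics, and kerma dosimetry.

## Embedded physics tables

K-line energies, relative intensities, K edges and fluorescence yields are
embedded as CSV fixtures with standard data-booklet values (intensity-weighted
Kalpha energies: Gd 42.75 keV, La 33.30 keV — the "43 keV" and "33 keV"
imaging peaks).

No cross-section library is bundled with the package's dependencies, so the
mass-attenuation tables in `inst/extdata/mass_attenuation.csv` are generated
by a compact empirical parameterization (see `tools/make_physics_tables.R`):

* **Photoelectric.** For heavy elements the total photoelectric coefficient
  just above the element's own K edge is taken from the screened-hydrogenic
  threshold cross section (2 x 6.30e-18 cm^2 / (Z - 0.3)^2 per atom) times
  the jump-factor correction J/(J-1) for the L and M shells; the coefficient
  decays as (E_K/E)^2.75 above the edge and continues below it divided by the
  jump factor J (no L-edge structure — smooth continuation, adequate above
  ~5 keV where this system operates). Light elements are anchored at 10 keV
  to the NIST water photoelectric value and scaled as Z^4.6/A.
* **Incoherent.** Exact Klein-Nishina total cross section per electron times
  Z N_A / A, with an empirical binding-suppression factor
  1 - exp(-E / 6.85 sqrt(Z)).
* **Coherent.** Z^2.8/A scaling with E^-1.9 energy decay, calibrated to water
  at 30 keV.

The resulting water totals agree with the NIST anchors to within ~2-3% over
10-150 keV (asserted in the test suite), which is the accuracy class needed
here; the tables are *model output*, documented as such, not copies of a
published compilation. The K-edge discontinuity is represented by two grid
points an epsilon apart so that log-log interpolation never crosses an edge.

`photoelectric_edge_ratio()` compares elements on *mass* attenuation
coefficients (cm^2/g), because every concentration in the phantom studies is
mass-based (mg/mL); on this basis La/Gd evaluates to ~1.41, consistent with
the ~1.5 commonly quoted. (Per atom the ratio would be ~1.26.)

## Source spectrum

`source_spectrum()` is the analytic tube model: a Kramers bremsstrahlung
continuum (photon fluence per unit energy proportional to Z (kVp - E)/E) plus
the anode's characteristic K lines when kVp exceeds the anode K edge, filtered
through the beryllium exit window (254 um default) and normalized to unit
fluence on a 0.1 keV grid. The characteristic-to-continuum balance of a
reflection-target Mo tube is not derivable from first principles at this
level; it is exposed as `char_fraction`, whose default (0.45 of the exit
fluence in the Mo K lines) reproduces the defining spectral property of this
system: most of the emitted beam *energy* lies below 21 keV — below both
imaging K edges — which is also why high-pass filtration cuts the phantom dose
by roughly an order of magnitude while leaving the XRF excitation unchanged.

This thin-target continuum is the model's single most influential
simplification: a thick-target (electron-transport) spectrum is somewhat
harder inside 39-50 keV, which matters for the Gd:La comparison discussed
below.

## Geometry

All placements derive from three printed numbers: 82 mm opposite-panel
spacing (detector planes at 41 mm from the axis), 14 mm collimator thickness,
and the 1:2 minification, which fixes the pinhole plane at 82/3 = 27.33 mm.
The pinhole layout is not printed. Placing pinholes directly behind their
region centers with panel-normal axes would leave the FOV center invisible to
12 of the 16 pinholes per panel (its image would fall outside their assigned
regions), so the constructor instead places each pinhole on the ray from the
FOV center to its region center, with its axis aimed at the FOV center: each
pinhole then images the FOV center onto the center of its own region — the
compound-eye intent — and the per-pinhole minification along its viewing ray
is exactly 1:2.

A consequence worth stating plainly: with ideal binary-disk apertures the
geometric sensitivity at the FOV center is bounded by
96 A / (4 pi 27.33^2) = 0.80% even before the off-axis pinhole offsets are
applied, and evaluates to 0.703% for the constructed layout
(`analytic_sensitivity()`; the ray-trace MC in `geometric_sensitivity()`
agrees within its standard error). The ~0.9% design figure for this class of
aperture therefore must include knife-edge penetration (a sensitivity-
effective diameter of ~1.13 mm would close the gap), which this package
deliberately does not model: apertures are ideal disks, and the collimator
shell is otherwise perfectly absorbing (rays reaching a pinhole from outside
its own panel's facet are rejected, the hexagon being convex).

Module mounting: the two lower modules of each panel's 2 x 2 are flagged as
physically inverted (180-degree rotation of their pixel readout);
`view_orientation()` exposes the flips that undo mounting and the
opposite-panel mirroring, and the merge step applies them implicitly by exact
3D ray back-projection of every hit pixel through its pinhole onto the
vertical plane containing the beam. This inversion handles the perspective
foreshortening of the 60-degree panels exactly rather than by a per-view
scale factor.

## Phantom

The two study fixtures are a 19 mm x 10 mm acrylic (PMMA, 1.18 g/cm^3)
cylinder with four PTFE tubes (4.7 mm outer / 3 mm inner diameter, walls at
2.2 g/cm^3 — a standard PTFE density, not printed in the source) whose
centers sit 5.5 mm off axis at 0/90/180/270 degrees (the exact angular
placement is not printed; 90-degree spacing matches the published figure).
Study I fills them with water and Gd at 3, 0.6 and 0.1 mg/mL; study II with
Gd:La mixtures 3:6, 3:3 and 6:3 mg/mL plus water. Solutions are modeled as
water plus the element at its stated mass concentration (dilute limit;
densities 1.000-1.009 g/cm^3).

## Forward simulator

For one scan position the simulator:

1. computes the depth-resolved expected K-emission profile along the beam
   (`xrf_yield_per_path`): surviving fluence x elemental photoelectric
   interaction probability restricted to spectrum bins above the K edge x
   K-shell fraction (J-1)/J x fluorescence yield, in 0.2 mm depth bins;
2. Poisson-samples *detected-candidate* photons per (depth bin, pinhole) from
   the solid-angle acceptance A cos(theta) / 4 pi d^2 — an exact thinning of
   the isotropic emission process — then samples each photon's exact emission
   point (uniform in the depth bin and the 1-mm beam disk), a target point on
   the aperture disk (aperture blur), attenuates it along its exit path
   through the phantom, applies the 1-mm CdTe photoelectric absorption
   probability, and projects it to a detector pixel;
3. generates single-scatter Compton background by forced detection: expected
   scatters per depth bin and 1-keV incident-energy bin, directed at each
   pinhole with the Klein-Nishina angular weight, with the scattered energy
   from the exact scattering angle; transport to the detector is identical to
   XRF photons;
4. applies charge sharing (probability 0.3 per event of a uniform split with
   one 8-neighbor — the scale reported for this detector family at 250 um
   pitch), then the Gaussian energy response interpolated between the
   measured FWHM anchors (0.5 keV at 35 keV, 0.88 at 60, 1.02 at 122), and
   assigns frames uniformly at the 2000 frames/s readout.

Omitted on purpose: multiple scatter, collimator scatter and penetration,
Cd/Te escape peaks, pulse pile-up, beam divergence and focal-spot blur.
Absolute beam flux is a configuration parameter (the source strength is not
derivable from the published system description); the package default of
1e8 photons/s through the 1-mm aperture makes the simulated
contrast-to-noise of the 0.1 mg/mL tube at one hour per position land in the
detectable range while the 10-minute acquisition falls below CNR 3 — the
qualitative behavior reported for the real system.

## Processing and image formation

`csd_filter()` implements charge-sharing discrimination exactly as specified
for this detector: within each (frame, module) every event with another event
in its 3 x 3 neighborhood is rejected (all members of a cluster are removed).
Its equivalence with a brute-force all-pairs oracle, its idempotence, and the
conservation properties are enforced in the tests. The two-point per-pixel
energy calibration (59.54 and 122 keV sources) locates each photopeak as the
count-weighted centroid of the highest bin +/- 3 bins in its half of the ADC
axis; synthetic construct-then-invert tests recover gains and offsets to
float precision.

Merging back-projects each kept event's ray through its pinhole to the beam
plane, bins the beam coordinate into 20 rows of 1 mm (the printed image
height; the axial coordinate is kept as 40 columns of 0.5 mm until
`collapse_columns()` sums it away), and accumulates per-row spectra in
0.25 keV bins. Net XRF per row uses a 3 keV window centered on the
intensity-weighted Kalpha energy with straight-line background fitted to
2 keV sidebands on each side ("close vicinity" is not quantified in the
source; 2 keV keeps the La window clear of the La Kbeta line). The sigma
grid propagates Poisson variance of the window plus the covariance of the
background fit. Columns of the 20 x 37 image are scan positions (0.5 mm
steps); no attenuation correction is applied, matching the published
processing.

## Quantification and dosimetry

CNR follows the defining ratio (tube ROI mean - center ROI mean) / center ROI
SD with 5 x 5 voxel ROIs; SNR is net/sigma per voxel; Rose detectability is
the inclusive test CNR >= 3 and mean SNR >= 5 (the source states the
thresholds without strictness; inclusive is this package's documented
choice). Linearity normalizes ROI means by the series maximum — any monotone
normalization leaves R^2 unchanged.

Dosimetry separates exact arithmetic (0.88 cGy/min x 10 min = 8.8 cGy per
position; x 37 positions = 325.6, reported as ~326 cGy) from the Monte-Carlo
kerma estimator: photons sampled from the (optionally high-pass-filtered)
spectrum interact along the beam with photoelectric/Compton/Rayleigh
branching; electrons deposit locally, Compton-scattered photons are not
followed (single-scatter transport), Rayleigh continues the photon. The
filtered (>= 21 keV) to unfiltered dose-rate ratio evaluates to ~0.12 — the
order-of-magnitude dose saving that motivates filtration — while the absolute
published rates (16.67 and 0.88 cGy/min) depend on the absolute source flux
and full electron transport and are outside this model's claims; only the
arithmetic built on 0.88 cGy/min is reproduced exactly.

## Scaled study conditions in the tests

Event-mode simulation of the real exposure (~3.6e11 incident photons per
position at one hour) is far beyond a desk-scale run, so the test and
acceptance simulations state and use scaled conditions:

* the Gd:La quantification factor and tube-localization checks run with the
  Compton background generator off — the windowed linear-background
  subtraction is unbiased with respect to the background, so this is pure
  variance reduction; exposures are chosen to emit >= 2e5 XRF photons per
  tube (deficit factor) and >= 1e5 (linearity);
* CNR checks, which *are* background statistics, run with the background on
  at 2e8 incident photons per position on the five central scan positions
  (both the tube and the phantom-center background ROI live there), averaged
  over four seeds;
* localization uses 20 seeds per study at 7e9 (study I) and 2e9 (study II)
  incident photons per position. Localization is judged at a 1-mm tolerance
  on each axis (one 1-mm row; two 0.5-mm columns): the voxels are
  anisotropic, and because the 3-mm tube bore spans six columns, the
  per-column net counts at the tube rows are equal by chord geometry over
  the central +-1 mm — the peak *voxel* across the scan direction is
  intrinsically ambiguous at the half-millimeter scale, at any exposure.

What passing these tests shows is that the chain is geometrically and
statistically correct at the simulated scale; what they cannot show is the
absolute detection limit of the physical instrument, which depends on the
true source flux and measured background.

On the two-element study the simulation reproduces the qualitative published
findings — each element's image peaks at its own highest-concentration tube,
and the per-unit-concentration Gd response falls below La's by a factor that
is constant across tube positions. The factor itself evaluates to ~2.0 here
versus ~1.67 reported: the excitation-integral ratio is sensitive to the
continuum shape between the two K edges, and the analytic Kramers continuum
is softer in 39-50 keV than a thick-target spectrum. We kept the analytic
source model (it is the package's declared design) rather than introducing a
tuned anode self-filtration thickness; the physically expected electron
penetration depth in Mo (~10 um) changes the factor negligibly.

## Numerical choices

Depth bins 0.2 mm; spectrum grid 0.1 keV; processing spectra 0.25 keV
(matching the detector resolution scale); Compton sampler 1 keV incident
bins; profile rows clamp out-of-range back-projections to edge bins so that
counts are conserved exactly as integers; all simulators take explicit seeds
and record them in their metadata, and per-position seeds are `seed + j - 1`.
ROI placement maps object coordinates to the nearest voxel center.
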