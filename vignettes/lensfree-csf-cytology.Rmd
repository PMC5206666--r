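---
title: "Lens-free CSF cytology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lens-free CSF cytology: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(holocyte)
```

## The problem

Counting leukocytes and erythrocytes in cerebrospinal fluid (CSF) is the
first laboratory step in diagnosing meningitis: at or above 10
leukocytes/uL a specimen meets the biological pleocytosis criterion.
Manual chamber counting under a light microscope is operator-dependent;
specimens near the cutoff get classified differently by different readers.
`holocyte` implements an operator-independent alternative built on
lens-free (in-line holographic) microscopy: a CMOS sensor under a thin
counting chamber records the interference pattern ("hologram") of plane-wave
illumination diffracted by the cells, a reconstruction algorithm recovers a
complex image of the whole 29.4 mm^2 field of view, and a gating classifier
converts per-cell optical signatures into leukocyte/erythrocyte counts,
concentrations and a meningitis/non-meningitis call.

Because no clinical acquisitions are distributed with the package, a
synthetic phantom module (`phantom_params()`, `sample_scene()`,
`simulate_hologram()`) plays the role of the instrument. Everything the
analysis claims is therefore demonstrated on phantoms whose ground truth is
known, not on patients; see "What the phantoms do and do not show" below.

## Forward model

A scene is a set of thin cells in the object plane, a distance
`chamber_z` (default 1000 um) above the sensor. Each cell contributes a
raised-cosine cap of phase delay (peaking at `peak_phase`, quoted at the
625 nm red reference and scaled by `625 / lambda` for the other channels)
and of absorption; overlapping caps add in phase and in absorption. The
object-plane transmittance

\[ t(x, y) = (1 - a(x, y))\, e^{i\varphi(x, y)} \]

is propagated to the sensor with the band-limited angular-spectrum
operator, squared into an intensity, scaled to sensor counts, noised
(additive Gaussian at 30 dB SNR by default -- the sensor is otherwise
uncharacterised, so this figure is an explicit assumption) and quantised to
the 16-bit range. The three LED bands are represented by their centres:
625, 527.5 and 457.5 nm.

Two phantom choices deserve justification because nothing in the
acquisition geometry fixes them:

* **Cell property ranges.** Erythrocyte diameters 6-8 um and leukocyte
  diameters 7-30 um; peak phases 0.5-1.2 rad (erythrocytes) and
  1.6-3.5 rad (leukocytes) at 625 nm, so that the two populations straddle
  the 1.38 rad gate the classifier uses -- which encodes the method's core
  assumption that leukocytes carry the larger phase shift.
* **Spectral absorption.** Erythrocyte absorption is drawn from 0.35-0.6
  *in the blue channel* and scaled by (1, 0.6, 0.2) across blue/green/red,
  following the shape of the haemoglobin spectrum (very strong towards the
  Soret band, weak in the red). Leukocytes are near-transparent
  (0.05-0.15, spectrally flat). This single physical fact produces, inside
  the phantom, the channel asymmetry the method exploits: the blue channel
  shows every cell as a compact dark disk (best detection), while the red
  channel sees erythrocytes as weak, clean phase objects (best per-cell
  signatures).

## Propagation

`propagate()` implements the angular-spectrum transfer function
\(H(u,v) = \exp(i \frac{2\pi}{\lambda} z \sqrt{1 - (\lambda u)^2 -
(\lambda v)^2})\) with evanescent frequencies zeroed. The angular spectrum
is the exact transfer function of scalar diffraction; at sub-millimetre
distances and 1.67 um pitch the paraxial (Fresnel) approximation it
generalises starts to degrade, so the exact kernel is used throughout.
Numerical choices:

* frames are embedded in a 2x-larger grid before the FFT and cropped
  after. The padding value is the *border mean*, not zero: a hologram's
  background sits near its mean count, and a zero pad would create a huge
  artificial edge whose diffraction ripples across the entire
  reconstruction (this is visible and catastrophic in practice);
* `pad = FALSE` gives the purely periodic transform, which is exactly
  unitary on the propagating band -- the form used by the energy and
  round-trip tests;
* the propagator is validated against an independent Rayleigh-Sommerfeld
  direct summation. The discrete RS sum is only a valid quadrature where
  the sampled kernel resolves its own fringes, so the comparison uses a
  smooth band-limited source and is evaluated inside that cone, where the
  two methods agree to ~1e-9 relative RMS.

## Reconstruction

`backpropagate()` treats \(\sqrt I\) as a real sensor-plane field and
propagates it back to the object plane; the missing phase leaves the twin
image superimposed. `phase_retrieval()` minimises the amplitude
data-fidelity loss \(\| |P t| - \sqrt I \|^2\) by gradient descent on the
object-plane transmittance with the physical constraint \(|t| \le 1\)
projected after every step; steps are halved until the loss does not
increase, so the recorded trace is non-increasing by construction, and the
iteration starts from the back-propagation (zero iterations reproduce it
exactly). Thirty iterations at step 1.0 are the default; regularisation
defaults to off (`reg_weight = 0`) since nothing beyond the modulus
constraint proved necessary on phantoms.

Both reconstructions are rotated so the background mean phasor has zero
phase ("piston removal"). The absolute phase of a reconstruction depends on
\(z_0\) modulo the wavelength and is physically meaningless; if the
background happens to sit near \(\pm\pi\), every small per-cell phase
excursion wraps and the (deliberately unwrapping-free) phase-amplitude
gate misreads whole populations. Referencing the background to zero costs
nothing and removes the failure mode.

### Autofocus

`autofocus()` scans back-propagation distances (default 500-1500 um at
20 um, a coarse-then-fine two-stage scan) and maximises the *kurtosis* of
the module image's deviation from its median, with parabolic refinement.
Kurtosis rather than the more traditional Tamura coefficient (still
available via `metric = "tamura"`): the Tamura focus is a *minimum* for
phase-dominated cells but a *maximum* for absorbing ones, and on mixed
scenes it settles 60-120 um off; the kurtosis criterion -- "at focus, a
sparse scene is heavy-tailed" -- localises the plane for absorbing cells,
phase cells and mixtures alike. `refine_focus()` then rescans a +-20 um
bracket with a dip-depth criterion.

On heavily crowded frames (haemorrhage-level densities) no single-scan
sharpness metric proved reliable: the near-sensor speckle of overlapping
diffraction patterns can out-score the true plane. `analyze_specimen()`
therefore keeps every prominent, well-separated local maximum of the focus
trace (up to two candidates) and lets the detection stage arbitrate: the
candidate plane that yields more confirmed cells wins. Sparse specimens
present a single dominant peak and pay no extra cost.

A subtlety worth stating: a phase-carrying cell is a micro-lens and
displaces its own plane of sharpest contrast by 15-25 um from the object
plane. Autofocus accuracy is therefore quoted on pure-absorption phantom
cells (where the focus is well-defined; errors are then a few
micrometres), and the detection stage absorbs per-cell shifts by
evaluating its confirmation dips over a +-20 um bracket about the focus
rather than at a single plane.

## Detection

Cells are detected on the blue-channel module image defocused by
`detection_dz` (default +250 um), where each cell presents a circular
diffraction pattern. `detect_cells()` is a gradient-oriented circular
Hough transform: edge pixels (top decile of gradient magnitude) vote along
their gradient direction at radii 2-10 px; accumulators are normalised by
circumference so a score of 1 means a fully supported perimeter; peaks are
5x5 local maxima above `accumulator_threshold` with near-duplicates
suppressed. The Hough parameterisation is not fixed by the method
description anywhere, so all knobs sit in `pipeline_config()`.

Raw Hough candidates are then confirmed against the in-focus
reconstruction (`confirm_detections()`): the centre is refined to the
local minimum of the smoothed module image, and the candidate must show a
3x3-mean dip of at least `dip_min` (default 0.09 on the unit-background
scale) below the median, with the dip evaluated as the maximum over a
+-20 um focus bracket. This stage is what separates faint erythrocytes
from the residual twin-image ghost rings of strong leukocytes -- ghosts
carry ring-like Hough support but no compact in-focus dip. The dip in the
red (analysis) channel is recorded as annotation (`dip_confirm`); it is
not a veto by default because erythrocytes are legitimately faint in red.
Diameters are re-estimated from the full width at half depth of the
in-focus radial dip profile, which tracks the physical cell better than
the Hough radius at a defocused ring.

## Per-cell signatures and gating

`compute_z_profiles()` samples the reconstructed complex field at each
confirmed centroid over 41 planes spaced 20 um (+-400 um about the focus
plane): `module = |field|`, `phase = arg(field)`, never unwrapped. The
span/count pair is configurable; 41 planes at 20 um is the default grid.
Within `analyze_specimen()` the sample is the 3x3 complex mean around the
centroid rather than the single pixel (the single-pixel option remains the
`compute_z_profiles()` default): at haemorrhage-level densities the
single-pixel phasor picks up enough coherent neighbour and twin clutter to
swing past \(\pm\pi\), inflating phase amplitudes to ~2pi and flipping
erythrocytes to leukocytes wholesale; the 3x3 mean suppresses the clutter
while preserving the cell's own spatially smooth signature.

Classification (`classify_cells()`) is by gates:

* **phase gate** -- profile amplitude (max minus min of the phase values)
  above 1.38 rad means leukocyte. No unwrapping is performed, by design: a
  genuine wrap means a phase excursion larger than any erythrocyte
  produces, so wrapped profiles are (correctly) gated as leukocytes.
  The 1.38 rad value is taken as canonical (its "80 degrees" gloss is
  arithmetically loose -- 80 deg = 1.396 rad).
* **module gate** -- a module-profile minimum more than 60 um above the
  focus plane, or no interior minimum at all, marks an outlier signature
  (typically a granular leukocyte) and overrides the phase gate towards
  leukocyte. "Well above" is not quantified anywhere, so the 60 um
  (three stack steps) default is this package's choice.
* **diameter gate** -- available for comparison (`mode = "diameter"`), and
  deliberately weak: at ~2 um resolution, erythrocytes (6-8 um) and small
  lymphocytes (7-8 um) overlap.

Counts become concentrations through the chamber geometry: the frame area
with sides rounded to 0.1 mm (full sensor: 6.4 x 4.6 = 29.44 mm^2) times
the 0.1 mm chamber depth, about 3 uL per acquisition. The specimen call is
positive when the leukocyte concentration reaches 10 cells/uL (inclusive
`>=` by default; the strict convention is a flag) *and* the erythrocyte
concentration stays below 4000 cells/uL; above both limits the specimen is
negative with a haemorrhage flag, since massive blood contamination
explains the leukocytes.

## Evaluation utilities

`roc_curve()` sweeps "score >= threshold -> positive" over all distinct
scores (ties collapse; endpoints at (0,0) and (1,1)) and is tested for
exact agreement with a brute-force per-threshold confusion-matrix oracle.
`sensitivity_specificity()` is the standard confusion-matrix pair.
`interoperator_stats()` reproduces the manual-counting variability
analysis: five operators' counts per specimen, a 3-of-5 consensus class at
the 10 cells/uL cutoff, and the fraction of specimens misclassified by at
least one operator, overall and within each consensus class, rounded
half-up to one decimal. `synthetic_operator_counts()` ships a
deterministic 72-specimen table whose consensus structure matches the
published study summary (12/72 discordant overall, 9/44 among
consensus-negative, 3/28 among consensus-positive); the individual count
values are synthetic.

## Problem sizes used by the tests

The packaged test-suite and `scripts/acceptance.R` work at desk scale:
propagator checks at 256^2 (oracle instances at 64^2), phase retrieval on a
512^2 noiseless single-cell phantom, detection on ten 512^2 phantoms with
90 cells at 30 dB SNR, autofocus on twenty single-cell phantoms at 256^2,
and the end-to-end classifier on twenty 256^2 phantoms spanning three
regimes -- cell-free/negative (0 leukocytes, 15 erythrocytes),
meningitis-positive (4 + 20) and haemorrhage (3 + 90, i.e. erythrocytes
above 4000/uL at this frame's 0.016 uL analysed volume). The full
3840 x 2748 sensor is supported by the same code path.

## What the phantoms do and do not show

The phantom reproduces the acquisition geometry, diffraction physics,
shot-to-shot noise, class-dependent size/phase/absorption distributions
and the crowding of haemorrhagic specimens. It does not reproduce:
leukocyte internal granularity and texture (the module-gate's "granular
leukocyte" outliers arise here only via profile shape, not via real
granule scattering); cell motion between the three sequential exposures;
non-cellular debris and protein background of clinical CSF; aberrations,
source partial coherence (the LED-pinhole source at ~5 cm is treated as an
ideal plane wave, with no spherical-wave magnification correction) or
sensor fixed-pattern noise. Passing the packaged checks therefore
demonstrates that the algorithms recover what this forward model encodes
-- it does not certify clinical sensitivity/specificity, which in the
original study could only be established against confirmed diagnoses.

## Known limitations

* Phase retrieval uses a generic amplitude-fidelity gradient scheme with a
  modulus constraint; the original instrument's exact update rules are not
  public, and no sparsity/smoothness regularisation is applied by default.
* The diameter estimate saturates for cells larger than ~2 x 12 px and is
  resolution-limited below ~2 px radius; the classifier does not rely on
  it by default.
* Autofocus assumes one dominant object plane; specimens with cells
  distributed through the full 100 um chamber depth rely on the +-20 um
  confirmation bracket and per-cell z refinement would be needed beyond
  that.
* At erythrocyte concentrations far above the haemorrhage limit
  (>> 10^4 cells/uL) overlapping diffraction patterns degrade detection
  recall; the specimen-level call remains correct as long as the recovered
  erythrocyte concentration stays above the 4000 cells/uL limit, but
  per-cell counts are underestimates there.
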