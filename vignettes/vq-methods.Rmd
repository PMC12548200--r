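---
title: "Methods: regional V/Q imaging on a digital thorax phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional V/Q imaging on a digital thorax phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqpipe)
```

`vqpipe` implements a complete measurement chain for regional pulmonary
perfusion and ventilation from CT, together with the agreement statistics
used to validate the perfusion surrogate against fluorescence-labelled
microspheres (FLM). Because real animal data of this kind are not openly
available, the package ships a synthetic thorax phantom with exact ground
truth; this vignette explains the models, the parameters that matter, the
numerical choices, and precisely what passing the phantom-based tests
does and does not establish about real data.

## Dual-energy decomposition

A dual-energy acquisition delivers two effective X-ray spectra. Iodine
raises attenuation in the low-energy spectrum by a fixed factor *r* (the
iodine ratio) relative to the high-energy spectrum, while water-equivalent
tissue attenuates (to good approximation) equally in both. Writing *V*
for the virtual non-contrast value and *I* for the iodine enhancement in
high-energy HU, each voxel satisfies

$$HU_{low} = V + rI, \qquad HU_{high} = V + I,$$

a 2×2 linear system solved exactly per voxel:
$I = (HU_{low} - HU_{high})/(r-1)$, $V = HU_{high} - I$. The system
degenerates as $r \to 1$, which is why `decomposition_config()` rejects
$r \le 1$; the default $r = 1.46$ is typical of a split-filter (twin-beam)
scanner, whose modest spectral separation also explains the noise
amplification below.

Vendor implementations add a proprietary noise-minimisation objective. We
deliberately implement the plain linear solve plus an optional isotropic
Gaussian smoothing of the iodine image (`smoothing_sigma_vox`, default 0)
as a transparent surrogate: the linear solve is the part that carries the
physics, and everything downstream is invariant to smooth noise shaping
because perfusion maps are sum-normalised. Negative iodine values are
unphysical noise and are clipped to zero by default
(`clip_negative_iodine`). For independent per-spectrum noise of standard
deviation $\sigma$, the iodine image noise is
$\sigma\sqrt{2}/(r-1) \approx 3.1\,\sigma$ at $r = 1.46$ — the price of a
small spectral separation, and a property the test suite verifies
against theory.

`mixed_image()` returns $w\,HU_{low} + (1-w)\,HU_{high}$; the blending
weight used by scanner consoles is not standardised, so $w$ is exposed
with default 0.5.

## Perfusion maps and regions of interest

Assuming a constant iodine concentration in the perfused blood during the
scan, iodine enhancement is proportional to the perfused blood volume per
voxel. `perfusion_map()` restricts the iodine image to the lung
parenchyma, excludes large vessels (segmented by 26-connected threshold
region growing from seed points), clips negatives, and normalises by the
sum; a region's sum is then its fraction of total perfused blood volume
(PP_DECT). An alternative normalisation by the blood-pool concentration
from a reference vessel would yield absolute blood volume; it is not the
default because the regional *fractions* the agreement analysis uses are
invariant to the overall scale.

Three ROIs are built per scan: the whole right lung, and the left lung
split along the axial direction into two equal-volume halves
(`split_rois()`; the split slice is the first at which the cumulative
left-lung voxel count reaches half the total, with the tie slice assigned
caudally). ROIs are the *delineated lungs*: vessels inside a lung count
as ROI volume but contribute nothing to the perfusion map. Regional
values are divided by ROI tissue mass derived from the VNC image via the
water-equivalent convention $\rho = 1 + HU/1000$ g/ml (clipped to
$[0, 1.1]$), and the three values renormalised to sum 1. Mass
normalisation is applied at ROI level — a ratio of sums — rather than per
voxel, which would divide by near-zero masses in well-aerated lung.

## Ventilation maps

Gas fraction follows directly from CT attenuation,
$F_{gas} = HU / -1000$, clipped to $[0,1]$. Given a deformable mapping
$T(x) = x + u(x)$ from end-expiratory to end-inspiratory coordinates, the
tidal gas-volume change per end-expiratory voxel is

$$dV = F_{gas,ei}^{@ee}\,|J| - F_{gas}^{ee},$$

where $F_{gas,ei}^{@ee}$ is the end-inspiratory gas fraction resampled at
$T(x)$ (trilinear) and $|J|$ the Jacobian determinant of $T$, i.e. the
local volume expansion. $|J|$ is computed from the displacement field in
world (mm) coordinates by central finite differences, one-sided at the
volume boundary; on affine fields this is exact to rounding, which the
tests check at 1e-6.

Registration itself is a pluggable contract. The package bundles two
engines: a ground-truth passthrough (`reg_engine_truth()`), used to test
everything downstream of registration in isolation, and a small
multi-resolution demons-style registrar (`reg_engine_demons()`) for
demonstrations. The demons defaults (three levels, 40/30/30 iterations,
fluid smoothing σ = 2.5 voxels, diffusion smoothing σ = 0.4 voxels) were
chosen so that a known 3-voxel translation of a smooth object is
recovered to well under half a voxel; like all first-order demons it
underestimates displacement in gradient-free regions, so production use
should plug in a dedicated registration engine through the same contract.
The mask-preparation cascade used before registration on real data —
morphological opening (radius 2), closing (15) and dilation (10 voxel,
spherical elements) — is provided by `prepare_mask()` on an exact
Euclidean distance transform; the radii are voxel counts appropriate for
1 mm isotropic scans and should be scaled for coarser grids. The
"3×3×3 Gaussian kernel" used to denoise gas-fraction images is
interpreted as σ = 0.75 voxels truncated at radius 1, both configurable.

## Microsphere processing

The FLM assay yields one row per 12 mm tissue cube: coordinates, weight
$x_i$, and fluorescence per color. `normalize_fluorescence()` computes
$f_i/x_i$ for the lung cubes of one color and normalises to sum 1;
`cubes_to_rois()` assigns each cube the ROI label at its centre
coordinate (postmortem cubes retain no anatomy beyond their cutting-grid
position); `regional_flm()` sums per ROI and renormalises. Cubes whose
centre falls outside all ROIs are flagged unassigned and reported. In a
real experiment the postmortem cube frame must additionally be mapped to
the in-vivo scan frame; the phantom sidesteps that registration by
sharing one coordinate frame, and this is a genuine limitation of the
validation: coordinate-mapping errors present in real FLM data are not
modelled.

## Agreement battery

With paired regional fractions (one row per animal, timepoint and ROI)
the battery computes ordinary least squares of PP_DECT on PP_FLM with
$R^2_{adj} = 1 - (1 - R^2)(n-1)/(n-2)$ and the slope's t-test;
Bland–Altman bias with limits of agreement $\pm 1.96\,s_d$ (sample
standard deviation); and quadrant concordance of between-timepoint
changes. Changes are computed between consecutive timepoints in protocol
order within each (animal, ROI) series; a change belongs to the
ventilation-condition stratum of its *earlier* timepoint, so the switch
from two-lung to one-lung ventilation is a TLV-stratum change. Changes
that are exactly zero (|d| ≤ 1e-12) carry no direction and are excluded
and counted. The primary concordance is the percentage of non-zero change
pairs in quadrants I and III among all four quadrants; the literal
quadrant ratio (I+III)/(II+IV) is reported alongside, because a ratio
above 1 and a percentage above 50 convey the same direction-tracking but
only the percentage is bounded. `stratified_report()` emits one row per
condition, per ROI, and pooled.

## The phantom: what it emulates

`make_phantom()` builds a 64³ grid at 3 mm spacing by default (a real
study would use ~1 mm voxels over ~330 mm; the coarser desk scale keeps
an end-to-end run in seconds while preserving the 12 mm cube / 3 mm voxel
hierarchy). Its content:

- **Anatomy.** Two barrel-shaped lungs (generalised ellipsoids, exponent
  6 along the cranio-caudal axis), a central airway, and one bright
  vessel tube per lung. The right lung is scaled to about half the left
  volume — under the study design's right-sided pneumothorax the right
  lung is collapsed — which also gives the three ROIs comparable size.
- **Aeration.** Gas fraction falls ventro-dorsally (0.72 → 0.47, the
  gravitational gradient of a supine subject) and is apodised to zero
  over the outer 35% of the lung radius, so rendered images are smooth
  across the pleural boundary. The apodisation is what makes trilinear
  resampling of the end-inspiratory image accurate enough for the
  ventilation-recovery test; it also creates a dense rim which is *not*
  hyperperfused (perfusion is apodised the same way), since loading the
  rim would distort the cube census of the FLM estimator.
- **Breathing.** Each ventilated lung scales axially about its apex by
  `expansion_factor` (default 1.25). The scaling is applied on every
  z-column that intersects the lung (its axial shadow), which makes the
  displacement piecewise linear and the Jacobian exactly the expansion
  factor at every lung voxel — including apex and base, so the
  finite-difference check holds everywhere in the lung rather than only
  in its interior. Gas fraction is transported along the deformation
  ($F_{ei}(T(x)) = F_{ee}(x)$), giving the closed-form truth
  $dV = (s-1)F_{ee}$. This transport rule is a deliberate simplification:
  it is smooth through the apodised boundary, at the cost of not
  conserving tissue mass exactly between phases.
- **Perfusion.** Proportional to tissue density with a mild apex-to-base
  rise in flow per unit mass (±10%), apodised at the rim; per-lung totals
  are set by the scenario: 0.5/0.5 under two-lung ventilation, and
  `perfusion_shift` to the ventilated left lung under OLV. The default
  schedule steps the shift 0.80 → 0.62 as the inhaled vasodilator dose
  increases, mimicking partial release of hypoxic vasoconstriction.
- **Iodine.** Concentration proportional to the perfusion fraction,
  scaled so the parenchymal mean is `iodine_mean_mgml` (default 2 mg/ml;
  with the default gain of 25 HU per mg/ml this yields ~50 HU mean
  enhancement). Only the product gain × concentration matters downstream.
  An optional multiplicative bias on the non-ventilated lung's iodine
  (`olv_iodine_bias`) models decomposition error in dense atelectatic
  tissue and lets the tests reproduce aeration-dependent disagreement
  between the methods.
- **Microspheres.** `n_microspheres` (default 15000, a desk-scale stand-in
  for the ~1.5×10⁶ used experimentally) deposition voxels drawn from one
  multinomial over the perfusion field, aggregated into 12 mm cubes
  anchored at the image origin; a cube is "lung" when at least half its
  voxels are parenchyma. Cube weight is the parenchymal tissue mass with
  2% Gaussian noise; fluorescence is count × color gain with 5%
  lognormal noise; color gains come from a fixed table and colors differ
  only by that scalar.
- **Noise.** 5 HU Gaussian noise per DECT spectrum by default. A single
  RNG stream per run is seeded once; draws occur in documented order
  (DECT noise, then microsphere deposition, fluorescence and weight
  noise, per timepoint).

### Geometry and the two regional functionals

The two regional estimators are structurally different functionals:
PP_DECT per ROI is a mass-weighted mean (Σpp/Σmass, renormalised) while
PP_FLM per ROI is a sum of intensive per-cube ratios, which scales with
the number of cubes in the ROI. They can only agree when the three ROIs
hold comparable cube counts and flow-per-mass is well behaved within each
ROI. The phantom's geometry constants were therefore fixed, once, with
that commensurability in mind: the axial lung position (centre 0.45,
half-length 0.35 of the grid) places the equal-volume split exactly on a
boundary of the 12 mm cube grid, and the right-lung scale (0.797) gives
the right ROI the same cube count as each left half. These are generator
design choices, not measurement steps; in a real study the analogous
mismatch between the functionals is part of what the agreement analysis
measures, and the phantom deliberately removes it so that the pipeline's
own errors are visible.

### What passing the phantom tests does not show

The phantom has no cardiac motion, beam hardening, scatter, breathing
irregularity, spatially correlated noise, contrast-bolus dynamics, or
postmortem deformation of the FLM cubes; lungs are smooth shapes without
airways beyond a stub or fissures. Tests passing on the phantom establish
that the implementation computes the stated quantities correctly and that
the statistical machinery behaves as designed — not that DECT perfusion
is accurate in vivo, which is exactly the question the original
experimental comparison addresses.

## Numerical conventions and problem sizes

Volumes are arrays indexed (x, y, z) with the world coordinate of voxel
centre $(i,j,k)$ at $((i,j,k) - 0.5)\cdot\text{spacing}$ and the origin
at the corner of the first voxel; displacement fields are in mm on the
fixed grid. Resampling outside the moving image returns gas fraction 0
and flags the voxel. The distance transform underlying the morphology is
exact (lower-envelope algorithm, Rcpp); ball membership uses
$d \le r$ with a 1e-9 slack against floating-point ties. Degenerate
inputs fail loudly: all-zero iodine in the mask, empty masks, zero-variance
regressors, ROIs without tissue mass, seeds below the region-growing
threshold.

The shipped tests and the acceptance script run the phantom at its 64³
default (≈39k parenchymal voxels, ≈600 lung cubes), 100 microsphere
repeats at n = 15000, and a 300-pair null-concordance control; a full
five-timepoint study takes a few seconds on one core.

```{r example, eval = FALSE}
run <- run_vq_study(vq_run_config("study_out", seed = 1))
glance(run$agreement)
autoplot(run$agreement, "bland_altman")
plot_vq_profiles(run$profiles)
```
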