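---
title: "Modelling flattened and flattening-filter-free linac beams at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flattened and flattening-filter-free linac beams at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Medical linear accelerators produce therapeutic photon beams by stopping a
narrow electron beam in a high-Z target. In the conventional configuration a
conical metal *flattening filter* sits below the primary collimator and
attenuates the forward-peaked bremsstrahlung cone most strongly on the
central axis (CAX), so that the lateral dose profile at depth is flat.
Removing the filter (flattening-filter-free, FFF) raises the dose rate
severalfold and changes surface dose, electron contamination, spectra and
their off-axis behaviour. On machines that raise the FFF electron energy so
the two depth-dose curves coincide ("pdd-matched" beams, here a 6 MV
flattened line against a 7 MV FFF line), those differences are subtle and
are best studied with a Monte-Carlo model commissioned against water-tank
scans.

`linacmc` implements such a model end to end at desk scale: a simplified but
physically explicit photon/electron transport engine through a parameterised
treatment head into a voxelised 40x40x40 cm water phantom, plus the
complete dosimetric analysis pipeline (depth-dose and profile metrics,
shoulder-point renormalization of FFF profiles, fluence spectra, paired
electron-kill runs for contamination, off-axis scans, phase-space files with
recycling) and the two-stage source-commissioning procedure.

# The beam model

## Primary electrons and bremsstrahlung

Primary electrons are sampled with Gaussian kinetic energy (mean
`mean_energy`, spread `energy_spread_sigma`, truncated at zero) and an
isotropic 2-D Gaussian focal spot of the given FWHM
(`sigma = FWHM / 2.355`), travelling along +z. The commissioned operating
points are 8.8 MeV for the FFF 7 MV line and 7.5 MeV for the flattened
6 MV line, both with 0.4 MeV spread and 1 mm spot.

Each primary emits one bremsstrahlung photon carrying a statistical weight
equal to the expected photon yield of a thick tungsten target
(classical radiative efficiency `6e-4 * Z * E / (1 + 6e-4 * Z * E)`
converted to a number yield by the mean emitted energy). The photon energy
follows a thin-target Schiff-type spectrum
`n(k) ~ (1/k)(1 - k/E + 0.75 (k/E)^2)` on `[0.05 MeV, E_eff]`, where
`E_eff` is the beam energy less half the collision loss in the target.
Self-attenuation in the target is applied as the depth-averaged
transmission weight `Tbar(k)`.

The emission *angle* is the convolution of two parts: the intrinsic
bremsstrahlung lobe with characteristic angle `m_e c^2 / (E + m_e c^2)`,
and the multiple-scattering tilt of the electron at its sampled emission
depth (Highland formula through `u x 1 mm` of tungsten). The energy
spectrum is deliberately sampled *independently* of the angle — a separable
virtual-source model. This is the one structural simplification that fixes
the qualitative off-axis physics: the FFF beam's mean photon energy is
radius-independent by construction (as observed on pdd-matched FFF
machines), while the flattened beam still softens off axis because its
filter is thickest on the CAX. The price is that genuine angle-energy
correlations of bremsstrahlung (a percent-level off-axis softening even
without a filter) are not represented.

Because the tilt grows like `sqrt(u)` with emission depth `u`, the radial
intensity at the phantom is a logarithmic mixture of Gaussians over the
intrinsic core — a gentle cone rather than a single Gaussian. With the
1 mm tungsten target this reproduces the published FFF unflatness scale
(about 1.1 at 10x10 cm up to about 1.9 at 40x40 cm) with no further
tuning; the effective scattering width is a physics-derived constant, not a
free parameter.

## Treatment head

The head geometry is parameterised, not proprietary: target at z = 0,
primary collimator exit at z = 10 cm (cone half-angle 0.28 rad, sized to
pass the 40x40 cm field), flattening filter centred at z = 12 cm (flat
mode only), square jaws at z = 30 cm with half-aperture
`field/2 x z_jaw/SSD` (fields are defined at the surface plane, SSD
100 cm), and the phantom surface at z = 100 cm. A phase-space capture
plane sits above the jaws at z = 25 cm. Photons outside the collimator
cone or jaw aperture are absorbed. Air fills the remaining column and
interacts by sampled photoelectric/Compton/pair events.

Contaminant electrons are produced explicitly — Compton and pair electrons
from the filter and the air column — and transported ballistically to the
phantom with Highland scattering and collision loss in air; electrons born
inside the filter must first escape the sampled residual filter thickness
(collision loss ~11.6 MeV/cm of steel, absorption when the residual range
is exhausted). This explicit production is what makes the electron-kill
experiment meaningful without a parametric contamination source.

## Flattening-filter design

The proprietary filter shape is replaced by a designed functional
equivalent: `design_flattening_filter()` computes the unfiltered radial
energy-fluence profile from the angular model, then solves, radius by
radius (monotone root bracketing of the spectral transmission integral),
the steel thickness `t(r)` that makes the transmitted energy fluence at the
surface uniform over 80% of a 40 cm reference field, flattening down to
the edge value. The returned profile is forced monotone non-increasing and
carries its design residual. Two properties are *not* designed in, on
purpose: there is no horn compensation for off-axis spectral softening at
depth (so the in-water profile at 10 cm is flat to several percent, not to
the design residual), and in-filter scatter is treated as removal at design
time (the transport replays it analogically).

## Water phantom transport

Photons undergo analog photoelectric, Compton (Klein-Nishina sampled by
inversion-rejection), and pair interactions; pair production splits the
available kinetic energy equally and the positron's annihilation emits two
back-to-back 0.511 MeV photons from its stopping point. Rayleigh
scattering, triplet production and atomic relaxation are out of scope.
Electrons use a condensed-history scheme: steps of at most 1 mm, energy
loss from the embedded stopping-power table, Gaussian (Highland) multiple
scattering per step, termination with local deposit below the range-cut
threshold. The conventional 1 mm range cut converts, per the embedded CSDA
table, to about 0.4 MeV in water. Bremsstrahlung from electrons in water
is neglected (sub-percent below 9 MeV). Energy bookkeeping is exact:
energy entering the phantom equals energy deposited plus energy leaving,
and the test suite asserts the closure.

## Cross-section data

No dosimetry data stack exists among the available dependencies, so the
interaction tables are embedded: the Compton channel is the closed-form
Klein-Nishina cross-section (exact in the free-electron approximation);
photoelectric and pair channels are derived from embedded total
mass-attenuation anchors of standard compilations, with the documented
convention that the channel total is their sum. Coherent scatter is not a
channel, so channel sums sit a few percent below literature totals between
0.1 and 1 MeV; at therapy energies the difference vanishes. Tungsten edge
structure is carried only by the anchor nodes.

# Scoring and estimators

Three tally families coexist:

* **Analog voxel grids** (5 mm over the whole phantom, or 1 mm over a
  restricted region for surface/buildup work) with per-batch sub-sums; the
  per-voxel uncertainty is the standard error over 10 batches.
* **Cylindrical CAX tally** (default radius 1 cm for analog runs) at the
  grid's depth resolution, which trades a little lateral resolution for an
  order of magnitude in variance — at desk-scale history counts a single
  1 mm voxel on the axis is hopeless, which is also why the published
  studies run billions of histories.
* **Collision-kerma track-length estimators** (`scoring_kerma()`): photon
  transport only, with `E * mu_tr(E) * track length` accumulated in a CAX
  cylinder (radius 2.5 cm) and a lateral slab at 10 cm depth. Beyond the
  buildup region collision kerma tracks dose to within about a percent,
  and every photon crossing contributes, so commissioning-quality curves
  need tens of millions rather than billions of histories. All tuning and
  penetration analyses use this estimator; surface dose, buildup and
  contamination use the analog tallies, which carry the electron physics.

Voxels are half-open boxes; the CAX column is the voxel whose centre is
nearest the axis with ties broken toward +x/+y. Profiles are single voxel
rows by default (an `n_avg` option exists for variance reduction). Off-axis
quantities follow the convention that an off-axis distance of `n` cm means
an `n` cm shift along *both* lateral axes.

The off-axis spectral scan additionally offers a **next-event estimator**:
because the angular emission density is known in closed form per history
(the separable model again), the expected contribution of every history to
each 5x5 mm scoring plane can be integrated directly, including the
deterministic filter and air attenuation along the ray. This is unbiased
for the primary fluence and neglects only in-scatter from head and air
(a sub-0.1% effect on these planes) while cutting the required histories by
roughly three orders of magnitude; the test suite cross-checks it against
the analog plane tally.

# Phase space and recycling

Particles crossing the capture plane are stored losslessly in a documented
little-endian binary format (`.bpsf`) with header and record checksums;
corruption errors name the failing byte offset. Recycling emits each
record `factor` times with independent azimuthal rotations about the CAX —
valid only above the jaws, where the head is rotationally symmetric, and
asserted against the plane position. Rotation cannot change a spectrum
(tested exactly) and reduces variance less than fresh histories would
(tested empirically with replicate runs).

# Source commissioning

`tune_source()` follows the two-stage protocol used to commission such
models: stage 1 scans the mean energy (0.1 MeV steps over 7-9 MeV for the
FFF line by default) and minimises the maximum absolute difference of
normalized depth-dose curves *beyond dmax* (the buildup region is excluded
because it is dominated by contamination and chamber effects in real
scans); stage 2 fixes the energy and scans spot FWHM and energy spread
jointly against the 10 cm profile. The *validation* statistic is the
maximum absolute point difference in percent (< 2% to pass) — but the
maximum of ~60 noisy tally points measures mostly the noise floor, so grid
*selection* uses the mean absolute point difference instead, computed
after fitting the relative scale of the two curves by least squares
(identical to dmax/CAX normalization in the noiseless limit, but immune to
the statistical error of the single normalization bin) and, for profiles,
restricted to in-beam points where the reference exceeds 10%. Both
statistics are tabulated in the result. All grid evaluations share one seed; the
spread's effect on the depth dose is weak, which is why it is tuned in
stage 2.

Three desk-scale choices matter here. First, the profile objective lives
in the penumbra, whose relative variance is several times the CAX one, so
stage 2 defaults to a larger history budget than stage 1
(`histories_stage2`). Second, the acceptance studies use a reduced grid
with 0.2 MeV energy spacing: at desk-scale history counts the depth-dose
statistic changes by only a few tenths of a percent per 0.1 MeV, so the
finer default grid is statistically meaningful only at the full published
history counts. Third, for the same reason the stage-1 energy pick is
noise-limited, and a one-step miss shows up in the *profile* (the FFF cone
width scales with the electron energy) as a 2%-scale mismatch; the
`refine_energies` option therefore lets stage 2 evaluate its grid over the
leading stage-1 candidates and select by the combined depth-dose +
profile objective. This keeps the two-stage structure while reproducing
the iterate-until-validated character of commissioning practice; the
classic single-candidate protocol remains the default.

# The synthetic reference generator

`synthetic_beam_model()` emulates water-tank scans with the statistical
structure the analysis assumes: depth dose = buildup x exponential x
inverse square with the buildup rate solved so the maximum falls at the
nominal dmax (19 mm FFF / 16 mm flat, effective attenuations chosen to
reproduce the published D20/D10 of each line); profiles = flat top or
linear FFF cone x error-function penumbrae x linear asymmetry; additive
Gaussian noise at 1 mm steps. Every profile metric has a fixture here with
an analytically known value (the 20-80% penumbra of an error-function edge
is `2 qnorm(0.8) sigma`, a triangular cone has exact slope and peak
position, and so on).

What the generator does *not* emulate — chamber volume averaging, scan-arm
positioning error, beam ripple — bounds what passing tests show: they
validate the analysis pipeline and the self-consistency of the simulator,
not agreement with any particular physical machine.

`simulator_as_reference()` closes the loop: the simulator's own curves,
generated at a hidden seed, serve as tuning reference, and the acceptance
suite requires the recovered source parameters to land within one grid
step and the tuned model to reproduce the reference within the 2%
validation bar.

# Numerical choices and degenerate inputs

* Inflection points: extremum of a Savitzky-Golay smoothed first
  derivative (window 5, quadratic), refined by a three-point parabola.
  Profiles without a resolved penumbra raise a metric error rather than
  returning a spurious inflection.
* Shoulder point: the published renormalization method names the shoulder
  but does not reprint its construction, so the operationalisation here is
  the maximum-magnitude point of the smoothed second derivative between
  15% and 90% of the way from the axis to the inflection, averaged over
  both sides; the rescaling is idempotent by construction.
* Slope windows: the [1/3, 2/3] half-profile interval on each side, shared
  between the slope metric and the straight-line fits of the peak-position
  statistic. Slopes are reported per centimetre, the scale on which the
  published per-field values are mutually consistent.
* Unflatness averages the left/right off-axis doses at 80% of the half
  field size; equal side slopes make the peak position undefined and raise
  a degenerate-geometry error.
* Batch streams: child seeds follow a fixed affine counter scheme in the
  master seed, so runs are bitwise reproducible and batches independent.
* Electron-kill runs transport the killed electron with scoring muted
  instead of dropping it, so the paired full/kill runs consume identical
  random streams (true common-random-number pairing; the test suite
  verifies the variance reduction of the paired difference).

# Problem sizes

The package's studies are sized for a single CPU: characterisation runs
use 2-4e7 histories on kerma tallies (sub-percent CAX statistics),
contamination pairs 4e7 analog histories on a 2.5 cm, 1 mm-resolution
surface cylinder, spectral scans 2-4e6 next-event histories, and the
commissioning validation 4.5e8 histories for reference and final runs
(both lateral axes scored and averaged) with 2.56e7 per stage-1 and
1.6e7 per stage-2 grid point. These are the package's chosen desk-scale
conditions; the published experiments behind the modelled machine used
billions of histories with recycled phase spaces to reach comparable
statistics on single voxels.

# Known limitations

* Contamination magnitudes are model-limited: with only filter and air as
  electron sources (no monitor chamber, mirror, or target-exit window),
  absolute contamination fractions and contaminant mean energies sit below
  the published machine's values; the orderings (flat above FFF, growth
  with field size) are reproduced and tested.
* dmax localisation at desk scale carries a few millimetres of statistical
  blur even on the 1 mm cylinder; the tests assert the buildup-region
  window and the flat-vs-FFF ordering rather than millimetre agreement.
* Collision kerma understates dose inside the buildup region by design;
  kerma tallies are therefore never used for surface or buildup claims.
* The angular table carries a ~2% normalisation bias relative to brute
  quadrature of the mixture density; only intensity ratios enter the
  filter design and spectral estimators, so this cancels everywhere it
  could matter.
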