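---
title: "Spectral dark-field signals and structure size: models, phantoms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral dark-field signals and structure size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(darkfieldr)
```

## The physical model

A Talbot–Lau grating interferometer converts ultra-small-angle scattering
into a loss of fringe visibility. The dark-field signal of a pixel is
$D = V_\text{sample}/V_\text{reference}$, the visibility reduction caused by
sub-pixel structure. At photon energy $E$ the interferometer is sensitive to
density correlations at the autocorrelation length

$$\xi_\text{corr}(E) \;=\; \frac{d_{S,G2}}{p_{G2}}\,\lambda
  \;=\; \frac{d_{S,G2}}{p_{G2}}\,\frac{hc}{E},$$

set by the sample-to-analyzer distance $d_{S,G2}$, the analyzer period
$p_{G2}$ and the wavelength. For isotropic multiple scattering the signal
follows

$$-\ln D(\xi_\text{corr}) \;=\; \sigma t\,[\,1 - G(\xi_\text{corr})\,],
  \qquad \sigma = \sigma_0\lambda^2,$$

where $t$ is the sample thickness and $G$ the projected real-space
correlation function of the electron-density fluctuations: the normalized
3D autocorrelation $\gamma(\mathbf r)$ of $\Delta\rho = \rho -
\langle\rho\rangle$ (computed via the correlation theorem), projected along
the beam axis and radially averaged in the perpendicular plane. $G(0) = 1$;
for media without long-range order $G \to 0$ at large shifts, and it may
legitimately become negative at intermediate shifts because the mean was
subtracted.

With a polychromatic source and a two-threshold photon-counting detector,
each counting bin mixes autocorrelation lengths. The package follows the
weighted-mean convention

$$\langle\xi_\text{corr}\rangle_w = \frac{\int_{E_1}^{E_2}
  \Phi_\text{eff}(E)\,V(E)\,\xi_\text{corr}(E)\,dE}{\int_{E_1}^{E_2}
  \Phi_\text{eff}(E)\,V(E)\,dE},$$

and combines monochromatic signals into a bin signal with the same weights,
$D_\text{bin} = \int \Phi_\text{eff} V D(E)\,dE / \int \Phi_\text{eff} V\,dE$
— validated in the tests against an explicit oracle that simulates
per-energy phase-stepping curves, sums their intensities over the spectrum
and retrieves the visibility with and without the sample.

The structural size measure on the other side of the correlation is the
mean chord length (MCL): the mean cavity intercept along isotropic uniform
random (IUR) test lines, the standard histological measure of alveolar
airspace size. Under IUR sampling a convex cavity has mean chord $4V/S$
(sphere of diameter $d$: $2d/3$), and a thin slab of thickness $t$ has mean
chord $2t$ once boundary-touching chords are excluded; these closed forms
are the package's stereology oracles.

## Key parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `d_s_g2` | 0.571 m | sample–analyzer distance of the reference setup |
| `p_g2` | 10 um | analyzer grating period |
| bins | [23, 64), [64, 120) keV | counting-bin thresholds |
| `response_fwhm` | 8 keV | Gaussian detector energy response (FWHM) |
| `design_energy` | 45 keV | visibility peak of the parametric model |
| `grid_step` | 0.5 keV | spectral quadrature step (trapezoid) |
| `sigma0`, `thickness_m` | 5e4 1/(m·Å²), 5 mm | scattering prefactor and sample thickness |
| `n_lines` | 5000–10000 | IUR test lines per MCL estimate |
| phantom grid | 128³ voxels, 2 um | default volume |

With this geometry the probed window is $\xi_\text{corr} \approx$ 0.6–3.1 um
across 23–120 keV, and the bin-weighted lengths come out near 1.6 um (low)
and 0.9 um (high).

The source spectrum is a Kramers bremsstrahlung shape filtered by 2 mm of
aluminium (tabulated mass attenuation, log-log interpolated), normalized to
unit integral — sufficient for weighting purposes; no detector pile-up,
charge sharing or fluorescence escape is modelled. The visibility spectrum
is parametric: a Gaussian peak at the design energy, a multiplicative dip
with its minimum at 64 keV (where the gold gratings become transparent
below their K-edge) and a secondary peak near twice the design energy; the
dip and peak parameters were set so the curve's maximum and minimum fall on
those stated features. A measured visibility curve can replace it via
`read_spectrum_csv()`.

The detector response enters as
$\Phi_\text{eff}(E) = \Phi(E)\cdot P(\text{recorded in bin}\mid E)$ with a
Gaussian response of configurable FWHM around the incident energy. Keeping
$\Phi_\text{eff}$ a function of *incident* energy is what the
$\xi_\text{corr}(E)$ weighting requires; `response_fwhm = 0` reduces to hard
truncation, and the two default bins then partition the spectrum exactly.
This one-parameter response is a deliberate simplification of a full,
calibrated detector response simulation.

## What the phantom generators emulate

Three seeded families mirror the structural classes of interest:

* `make_solid_spheres()` — dilute sphere phantoms whose autocorrelation and
  MCL are analytically known; placement by random sequential addition,
  voxel-centre membership.
* `make_hollow_spheres()` — thin glass shells around air cores with air
  between spheres (hollow microsphere fillers), optional lognormal radii.
* `make_voronoi_foam()` — closed polyhedral cells: a Voronoi tessellation of
  uniform seeds whose boundaries, thickened to the wall width, are material.
  Seed density is the single knob for cell size, hence MCL.

All generators return the exact binary phase map alongside a two-plateau
grayscale volume (material 1, air 0), so segmentation can be tested against
ground truth, and `add_microct_noise()` degrades the grayscale volume with a
Gaussian point-spread blur plus additive noise scaled to the grayscale
contrast. What the phantoms do **not** emulate: sub-voxel wall texture,
anisotropic or graded structures, reconstruction artifacts (rings, beam
hardening, streaks), partial-volume physics beyond linear blurring, or
correlated noise. Passing tests therefore demonstrate the correctness of
the analysis chain on ideal two-phase media with microCT-like degradation —
not robustness to every artifact of real tomography.

## Numerical choices

**Autocorrelation.** `autocorrelation_3d()` zero-pads to twice each
dimension so the FFT product is the linear (aperiodic) correlation — the
finite-volume overlap integral, verified against a direct triple-sum oracle
to 1e-10 on small volumes. The plain estimator multiplies the true
correlogram by a triangular overlap window $\prod_i(1-|r_i|/n_i)$; it is
bounded ($|\gamma|\le 1$) and is the default. An overlap-corrected
`normalization = "unbiased"` variant removes that damping for quantitative
comparisons with analytic correlation functions; it may exceed 1 where few
voxel pairs overlap. A `periodic` mode (circular correlation, no padding)
exists for parity checks and for synthetic fields that are periodic by
construction.

**Projection and radial averaging.** The beam axis is the first array axis;
the projected map is normalized at zero perpendicular shift so $G(0)=1$
exactly, then averaged over annuli one voxel wide *centred* on integer
radii. Centred bins keep the first nonzero $\xi$ at exactly one voxel — the
resolution floor of the method — and halve the bias that lower-edge binning
would introduce by pairing each $G$ value with a radius systematically
smaller than its annulus mean. A caveat discovered while validating against
Gaussian random fields: projecting along the beam collapses the statistics
onto a single plane of Fourier modes, so the tail of a single-volume $G$
estimate carries relative errors of tens of percent at 96³–128³; the test
suite therefore pools several field realizations before comparing with the
closed-form Gaussian decay (5% relative within one correlation length, 0.05
absolute out to two).

**Chord measurement.** Lines are IUR: direction uniform on the sphere,
offset uniform on a disc containing the volume's projection; this is the
sampling design under which the $4V/S$ and $2d/3$ identities hold. Each
line is sampled at a quarter-voxel step; the binary phase is interpolated
trilinearly between voxel centres and thresholded at 1/2, and chords
shorter than two voxels (the smallest representable feature) are discarded.
Both choices are deliberate: sampling the raw voxel staircase instead
inflates the interface area by roughly half, fragments grazing chords and
biases the sphere MCL from 26.7 to ~18 um, far outside the oracle's
tolerance. Chords whose run touches a volume face are excluded and counted,
implementing per-chord the rule that a cavity extending beyond the region
of interest must not contribute. The slab oracle retains a small (~3–4%)
downward bias from that same exclusion — near-grazing chords are
preferentially lost — which the 5% tolerance absorbs; enlarging the
in-plane extent shrinks it.

**Segmentation.** Otsu's threshold on a 256-bin histogram (implemented
internally; cavity = below threshold). On noiseless two-plateau phantoms it
recovers the generator's phase map exactly; at 5% contrast noise agreement
stays above 99%.

**Quadrature.** All spectral integrals use the trapezoid rule on a common
interpolated grid (0.5 keV default); halving the step moves the weighted
correlation length by well under 0.1%.

## Design of the end-to-end study

`run_study()` reproduces the qualitative headline: the quotient
$-\ln D_\text{low}/-\ln D_\text{high}$ rises with MCL. The default family
is five Voronoi foams on 128³ grids with seed counts 700, 120, 30, 30, 30
at voxel sizes 2, 2, 2, 4, 5 um and wall thicknesses 4, 4, 4, 8, 10 um,
spanning MCL ≈ 20–150 um — the range spanned by closed-cell foams and
hollow-microsphere packings used as lung-parenchyma surrogates. Three
choices deserve explanation:

* *Voxel size grows with cell size.* The field of view must hold tens of
  cells for a stable correlation profile and chord census; at fixed 128³
  that forces coarser voxels for larger cells, exactly as a microCT
  operator would trade resolution for field of view. Walls thicken with
  cells, as in real foams. At least 30 cells per volume keeps the
  realization-to-realization scatter of the quotient well below the
  between-material differences.
* *The PSF is one voxel.* Scanner blur tracks the reconstruction voxel, so
  the degradation model uses `blur_vox = 1` rather than a fixed physical
  width; this keeps the effective sharpness of the correlation profile
  consistent across family members with different voxel sizes.
* *Where the trend comes from.* All cells lie far above the probed window
  (0.6–3 um), where $1-G$ is nearly linear in $\xi$; in that regime the
  quotient approaches a structure-independent limit. Its residual MCL
  dependence has two cooperating sources: the curvature of $G$ within the
  window (stronger for finer structure, pulling the quotient down) and the
  nonlinearity of polychromatic averaging (strong scatterers — high surface
  density, low MCL — compress the low-bin mean of $D$ more). Both rise
  monotonically with MCL, and the study reports the Spearman rank
  correlation plus a strict-monotonicity flag rather than any quantitative
  slope. The published per-material quotients are *not* reproduced
  quantitatively: they reflect detector response overlap and material
  microtexture outside this model's scope.

`sigma0 = 5e4` 1/(m·Å²) with 5 mm thickness puts the low-bin signals in the
0.4–1.2 range typical of such measurements; the quotient is invariant to
the overall $\sigma_0 t$ scale except through the polychromatic
nonlinearity above.

Problem sizes throughout (128³ studies, 20 000 lines for the sphere oracle,
6 pooled 96³ realizations for the Gaussian check) were chosen as the
smallest at which the statistical tolerances above hold with margin.

## Worked-example fixture

`reproduce_worked_examples()` recomputes, from printed setup constants and
per-bin signals stored in `inst/extdata/worked_examples.json`, the two
weighted autocorrelation lengths and the wavelength-normalized signals
$-\ln D/\lambda_w^2$ for four materials in both bins, comparing at the
printed two-decimal precision. The EPDM entries are carried in the fixture
but flagged `compared = FALSE`: dividing its rounded per-bin signals by the
printed squared wavelengths yields 12.49 and 16.44 against published 12.60
and 16.00 — consistent with those two entries having been computed from
unrounded data upstream.

## Known limitations

* The correlation profile's first nonzero point sits at one voxel, while
  the probed $\xi$ window is sub-voxel to a few voxels; $G$ inside the
  window rests on linear interpolation from $G(0)=1$. This mirrors the
  resolution limit of the underlying method rather than hiding it.
* The dark-field chain assumes isotropy; no direction-resolved (tensor)
  dark-field analysis is provided.
* Beam hardening, charge sharing, fluorescence escape and sample-thickness
  dependence of the probed $\xi$ are out of scope.
* MCL estimates on slabs and other unbounded-chord geometries are heavy
  tailed; their standard errors understate the uncertainty of small
  samples.
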