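---
title: "Accelerated 3D EPR redox mapping: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated 3D EPR redox mapping: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eprredox)
```

## The measurement model

Continuous-wave EPR imaging of a nitroxyl radical records, for each
magnetic-field-gradient direction $d$ on the unit sphere, a first-derivative
spectrum. Under a gradient of magnitude $G$ the spectrum is the 3D Radon
transform of the spin density — the integral of the object over planes
$G\,(r \cdot d) = b$ — convolved along the field axis $b$ with the
zero-gradient lineshape. The package's forward model is therefore

$$ y_d(b) = \big(C\,R_d\,x\big)(b) + \varepsilon, $$

with $R_d$ the plane-integral projector, $C$ convolution with the
first-derivative line, and $\varepsilon$ additive white Gaussian spectral
noise. A nitroxyl probe with a $^{15}$N label has a two-line hyperfine
spectrum; acquisition centred on one of the two absorption peaks makes a
single-line model appropriate, and modulation broadening is absorbed into
the effective peak-to-peak linewidth rather than modelled separately.

Reduction of the probe to its EPR-silent hydroxylamine makes the signal
decay as $S(t) = A_0 e^{-kt}$; the voxelwise rate $k$ is the redox-sensitive
readout. Faster decay indicates a more reducing environment, as in tumor
tissue.

## Direction schedules

`golden_mean_directions(n)` places directions at
$z_i = 2\,\mathrm{frac}(i\phi_1) - 1$, $\theta_i = 2\pi\,\mathrm{frac}(i\phi_2)$
with $\phi_2$ the real root of $x^3 + x - 1 = 0$ and $\phi_1 = \phi_2^2$
(`GOLDEN_MEAN_1`, `GOLDEN_MEAN_2`). Two properties matter:

* any prefix of the sequence is itself quasi-uniform, so a long acquisition
  can be truncated retrospectively to emulate a shorter one (the package
  exploits this in `run_acceleration_experiment()`, and the prefix property
  is asserted exactly in the tests);
* the nearest-neighbour spacing is far more even than uniform-random
  sampling — `uniformity_score()` (coefficient of variation of
  nearest-neighbour angles) is roughly 0.1–0.2 for golden-mean sets against
  about 0.5 for random sets of the same size.

The index starts at $i = 1$: $i = 0$ would put the first direction exactly
at the pole. The schedule covers the full sphere with no antipodal
deduplication, matching acquisitions that scan a full sphere of gradient
directions.

## Forward simulation choices

**Plane-integral discretisation.** Each voxel's mass
(value × voxel volume × $G$) is split linearly between the two field bins
bracketing its projected coordinate. This conserves total mass exactly
(`sum(profile) * db = sum(v) * voxel_volume * gradient` for objects inside
the field of view) and makes the projector's adjoint cheap and exact. Mass
falling outside the sweep raises a warning instead of wrapping.

**Lineshape.** `lineshape_profile()` is the analytic derivative of a
unit-area Lorentzian or Gaussian absorption line, parameterised by the
peak-to-peak width read off a measured spectrum
($\Gamma_{FWHM} = \sqrt{3}\,\Delta B_{pp}$ Lorentzian,
$\sqrt{2\ln 2}\,\Delta B_{pp}$ Gaussian; both conversions are verified
against a dense-grid numerical oracle in the tests). The default is a
Lorentzian of 0.073 mT, typical of a perdeuterated $^{15}$N nitroxyl probe.
The convolution kernel is evaluated on a centred odd-length axis so that
"same"-mode convolution is zero-phase and its transpose is convolution with
the reversed kernel — a requirement for the exact adjoint test below.

**Default protocol.** 1.5 mT sweep in 100 ms with 30 ms flyback, 512 field
points, 40 mT/m gradient. These give a reconstruction field of view of
sweep/gradient = 37.5 mm, an intrinsic resolution of
0.073 mT / 40 mT m⁻¹ ≈ 1.8 mm, and scan times of 33.4 s for 256 projections
plus a zero-gradient reference, 16.8 s for 128 plus reference, and 266 s for
a 2048-projection phantom acquisition.

**Noise.** Additive i.i.d. Gaussian on the first-derivative spectra, the
standard CW-EPR assumption; the experiment runners express it as a peak
signal-to-noise ratio (peak |signal| across the full schedule divided by the
noise standard deviation) with default SNR 20, a realistic in-vivo figure.
All noise is seeded and bitwise reproducible, and the generators restore the
caller's RNG state.

## Reconstruction

### Compressed sensing (FISTA)

`fista_reconstruct()` minimises
$\|CRx - y\|_2^2 + \lambda_1\|x\|_1 + \lambda_2\,TV(x)$ with a monotone
(best-iterate) FISTA: a gradient step of size $0.95/L$ ($L$ from 10 power
iterations on $A^\top A$, seeded), then TV denoising with weight
$\lambda_2 \cdot$ step, then soft-thresholding with threshold
$\lambda_1 \cdot$ step, then an optional non-negativity clamp, with standard
FISTA momentum. Design choices where the method leaves room:

* **Monotone variant.** Plain FISTA is not monotone; with only 4 outer
  iterations (the default, after which the phantom reconstructions have
  converged visually and in objective) a non-increasing objective is both
  desirable and testable, so the best iterate is kept.
* **Prox order.** TV-then-L1 per iteration (composition documented as an
  approximate proximal operator of the sum); the reverse order is available
  via `prox_order = "l1_tv"`.
* **Inner TV solver.** Chambolle's dual projected-gradient scheme, isotropic
  3D forward differences, reflective boundaries, step 1/12 (the 3D operator
  norm bound), 10 inner iterations by default. The primal energy is
  non-increasing in the inner iteration count and within 1% of a long-run
  reference after 50 iterations on step signals.
* **Normalisation.** Spectra are scaled to unit maximum internally for
  numerical stability and the output volume is max-normalised; a time series
  of frames therefore needs `renormalize_series()`, which multiplies each
  frame by the mean double-integrated amplitude of its own spectra (a
  spin-count proxy) to restore the decay profile.
* **Non-negativity.** On by default (the reconstructed map is an intensity);
  `nonneg = FALSE` reproduces the unconstrained optimisation.
* **Presets.** $(\lambda_1, \lambda_2) = (0.1, 0.01)$ for high-SNR
  sharp-edged phantoms, $(0.01, 0.01)$ for lower-SNR in-vivo-like objects
  whose signal edges are softer — a strong L1 weight over-suppresses and
  distorts such distributions.

With $\lambda_1 = \lambda_2 = 0$ and many iterations the solver approaches
the least-squares solution (checked against a pseudo-inverse on an $8^3$
problem), and the operator pair passes the adjoint dot-product identity at
$10^{-15}$ relative — the property that gates every other CS test.

### Filtered back-projection

The analytic inverse of the plane-integral transform filters each profile
with a second-derivative ($|\omega|^2$) ramp and back-projects over the
sphere with weight $4\pi/n$ and constant $-1/(8\pi^2)$. Ahead of the filter
the lineshape is removed by Tikhonov-regularised Fourier division
(denominator $|L(\omega)|^2 + \mathrm{reg}\cdot\max|L|^2$, default
reg = $10^{-3}$). Two numerical points:

* The first-derivative kernel integrates to zero, so the profile baseline is
  invisible to the division; it is restored from the compact-support
  constraint that the padded profile vanishes on the guard bins.
* The exponentially decaying Lorentzian transfer function makes the
  sub-linewidth band unrecoverable at any regularisation: band-limited
  profiles round-trip within 1%, but thin-pillar profiles with cusps retain
  a ~12% relative L2 floor. This is physics (the 1.8 mm intrinsic
  resolution), not solver error.

The global scale is calibrated by reconstructing a unit impulse through the
same pipeline. Because the residual point-spread function is wider than one
voxel, extended structures reconstruct with a plateau bias relative to the
unit-peak convention; all quality comparisons in the package score each
method against its own full-schedule reconstruction (or normalise), so this
bias cancels where it matters.

## Image-quality metrics

`nrmse()` (RMS error over the reference's dynamic range), `mae()` (mean
absolute error after per-image max-normalisation) and `ssim()` implement the
three standard indicators. SSIM defaults to the windowed form — 3D Gaussian
weighting, $\sigma = 1.5$, 11-voxel support, $c_1 = (0.01L)^2$,
$c_2 = (0.03L)^2$ with $L$ the dynamic range of the pair — matching common
toolbox practice; the single-window global-statistics formula is available
with `method = "global"`. Volumes are scored in 3D; slice-wise use is a
matter of passing 2D-extracted arrays. Two comparison conventions are used
by the experiment runner: phantom studies score each method against its own
2048-projection reconstruction; in-vivo-style studies use the CS
256-projection map as the common reference, because an undersampled FBP map
is too noisy to referee.

`psf_fwhm_estimate()` fits a measured 1D profile as a boxcar of known width
convolved with a Gaussian and reports the Gaussian's FWHM — the operational
spatial resolution, estimated at 2.5 mm from phantom profiles on the real
instrument versus the 1.8 mm intrinsic limit.

## Synthetic data: what it does and does not emulate

`pillar_phantom()` builds the resolution phantom: ten 3.0 mm × 15.0 mm
pillars at 5.0 mm pitch in a 21.8 mm housing (1.06 mL of solution). Count,
pitch, diameter and length are as printed for the physical object; the
1-2-3-4 triangular row arrangement is an approximation of the drawing.
Partial volumes use 8×8 in-plane supersampling with exact end-cap overlap,
keeping total mass stable to <0.5% between 64³ and 128³ grids.

`two_compartment_leg_phantom()` is a deliberately simple stand-in for a
tumor-bearing leg: an ellipsoidal "leg" (8 × 8 × 12 mm semi-axes) of uniform
initial amplitude with an embedded 4 mm-radius spherical "tumor", decay
rates 1.00 and 1.36 min⁻¹ (the normal/tumor group means the mapping is
designed to distinguish). `decay_series()` evolves it as a clean exponential
at 5 frames of 16.8 s starting 30 s post-injection, timestamped at mid-scan
(the least-biased single timestamp for an exponential sampled over a finite
scan).

Not emulated: resonator sensitivity inhomogeneity (it cancels in decay
rates), vascular uptake and washout kinetics, motion, baseline drift, and
the spatial heterogeneity of real tumors. Passing the recovery experiment
therefore shows the pipeline is unbiased under its own model assumptions at
realistic SNR — not that real-animal maps carry no physiological confounds.

## Decay-rate mapping

`fit_decay_map()` thresholds the first frame at a fraction of its global
maximum (25% for rate maps, 15% for display masking), then fits
$S(t) = A_0 e^{-kt}$ per masked voxel: a log-linear ordinary-least-squares
initialisation on (clipped-positive) samples followed by a vectorised,
damped Gauss–Newton refinement with $k \ge 0$, up to 200 iterations;
non-finite fits are removed from the validity mask. The log-linear route is
available as `method = "loglinear"`. Only the early frames are fitted
(default: the first 5 of a series) because later frames of a fast-decaying
probe contribute mostly noise. Rates are reported in reciprocal units of the
series' time axis, and unit conversion is exact
(`convert_series_unit()`; $k$ scales by 60 between s and min).

`decay_histogram_stats()` and `roi_mean_rates()` (5×5 in-plane boxes by
convention) summarise the map the way mapping studies report it: a histogram
median over the masked volume and per-ROI means in normal and tumor tissue.

## Problem sizes and reproducibility

The packaged experiments use grids chosen for routine desk runs: the
acceleration study at 64³ with schedules 64–2048 (a few minutes on one CPU),
and the recovery study at 48³ with 128 projections × 5 frames × 20 seeded
replicates. The full-resolution setting of a real study (96³–128³) runs
through the identical code path, only slower. Every stochastic step takes an
explicit seed, the projector/backprojector pair is deterministic, and the
CLI writes a manifest (command, options, package version) beside each
output.

## Known limitations

* The projector assumes isotropic voxels and a uniformly spaced field axis.
* FBP's absolute intensity scale is convention-dependent (impulse-peak
  calibrated); use it for relative comparisons or normalise.
* The CS regulariser weights are empirical presets, not auto-tuned; a
  different SNR regime may need a different $\lambda_1$.
* Series renormalisation assumes the double integral of the spectra tracks
  total spin count; strong baseline artefacts in measured spectra would bias
  it, and the random-walk error of double-integrating noisy spectra grows
  with sweep width.
* The two-compartment recovery carries a small (~3%) downward bias common to
  both compartments, inherited from max-normalisation against a decaying
  global maximum; it cancels in the tumor/normal contrast.
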