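---
title: "Methods: benchmarking plasmonic nano-heaters with nanoheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking plasmonic nano-heaters with nanoheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoheat)
```

`nanoheat` is a computational platform for comparing plasmonic
nanoparticles as photothermal heat transducers. It covers the chain from
theory to readout: analytic electromagnetic cross-sections, inference of
single-particle surface temperatures and absorption cross-sections from
lipid-bilayer melting footprints, and an early-treatment-response
statistic for FDG-PET tumor volumes. Every stage has a matched synthetic
generator with known ground truth, so the whole pipeline is testable
without any experimental download.

## Optics: Mie theory for solid and coated spheres

A particle's usefulness as a nano-heater is set by its absorption
cross-section $C_{abs}(\lambda)$: the absorbed power is
$P = C_{abs}\, I$ at intensity $I$. For spheres and core--shell spheres
in a homogeneous medium these cross-sections are analytic. The
partial-wave coefficients $a_n, b_n$ give

$$C_{ext} = \frac{2\pi}{k^2}\sum_n (2n+1)\,\mathrm{Re}(a_n+b_n),\qquad
  C_{sca} = \frac{2\pi}{k^2}\sum_n (2n+1)\left(|a_n|^2+|b_n|^2\right),$$

with $k = 2\pi n_{med}/\lambda$ and $C_{abs} = C_{ext} - C_{sca}$.

Numerical choices:

* The internal logarithmic derivative $\psi_n'/\psi_n$ is computed by
  downward recurrence (started 15 orders plus $|z|$ above the truncation
  order), which is stable for strongly absorbing gold where upward
  recurrences blow up.
* For the coated sphere, the shell standing wave is carried as an
  explicit $\psi - A\chi$ pair; $\psi$ at complex argument comes from a
  normalised downward (Miller) recurrence and $\chi$ from the upward
  recurrence, which is stable because $\chi$ is the growing solution.
  The interface-matching coefficients follow from continuity of the
  tangential-field impedance ratios ($\psi'/(m\psi)$ for TM,
  $m\,\psi'/\psi$ for TE) at both boundaries. The implementation is
  validated against a degenerate-shell identity with the solid-sphere
  path and against the quasi-static coated-sphere polarizability closed
  form, which discriminates the TM/TE pairing.
* Series truncation uses the Wiscombe rule
  $n_{max} = \lceil x + 4x^{1/3} + 2\rceil$; doubling it changes
  $C_{abs}$ by less than $10^{-8}$ relative.
* A tiny negative $C_{abs}$ (below $10^{-6}$ relative) is clamped to
  zero; anything larger raises a convergence error instead of being
  hidden.
* Gold uses the Johnson & Christy tabulation packaged with the source
  (linearly interpolated in both index parts; spline interpolation was
  checked and moves the computed peaks by at most 1 nm). Silica is
  $n = 1.45$, water $n = 1.33$, both dispersionless. Peak positions are
  refined by a parabola through the three grid points around the
  maximum; the default grid is 400--1100 nm in 1 nm steps.

The glass coverslip of the single-particle experiment is *not*
modelled: spectra are for a homogeneous water medium. This is the
documented approximation of the optics module and its main known
limitation. Substrate coupling and sample polydispersity red-shift
measured resonances relative to homogeneous-medium Mie theory, and the
quoted experimental peak positions for the two 150 nm particles sit
20--40 nm red of what any homogeneous-medium calculation with standard
gold optical constants yields; the 80 nm sphere, whose resonance is
interband-pinned, agrees to 1 nm. Cross-section magnitudes and ratios
at the therapy wavelengths are much less sensitive to this and agree
closely.

## Single-particle thermometry

A continuously irradiated nanoparticle acts as a point heat source. In
steady state the temperature increase at distance $D \ge R$ from its
center is

$$\Delta T(D) = \frac{C\,I}{D},$$

where $C$ (units K·m³/W) bundles the absorption cross-section and the
heat conductivity of the surroundings. The supported-bilayer assay
measures this profile through the gel-to-fluid transition of a DC15PC
bilayer at $T_m = 33.8\,^\circ$C: the melted, brightly fluorescent
footprint ends exactly where the local temperature has fallen to
$T_m$. At the footprint radius $D_m$,
$\Delta T(D_m) = T_m - T_{ambient}$, so one footprint fixes

$$C = \frac{(T_m - T_{ambient})\,D_m}{I}.$$

From $C$ follow the surface temperature
$\Delta T_P = C\,I/R$ and, through the steady-state conduction balance,
the experimental absorption cross-section

$$C_{abs} = \frac{4\pi\,k\,R\,\Delta T_P}{I} = 4\pi\,k\,C,$$

with $k = (k_{glass} + k_{water})/2 = 0.855$ W/(m·K) the simple average
of the two half-spaces bounding the particle. The second equality is an
algebraic identity, independent of $I$ and $R$; the test suite holds it
to $10^{-12}$ relative. All constants ($k_{glass} = 1.1$,
$k_{water} = 0.61$ W/(m·K), $T_m = 33.8\,^\circ$C,
$T_{ambient} = 26.7\,^\circ$C) live in `thermal_environment()` and are
overridable; they are defaults, not hard-coded call-site values.

Units: user-facing functions take intensities in W/cm² and lengths in
µm/nm, the conventions of the experiment; everything is converted to SI
internally, and `C` is reported in K·m³/W.

Heat-conversion slopes (`fit_heating_slope()`) are zero-intercept
ordinary least squares of $\Delta T_P$ against power, because the model
forces $\Delta T(I = 0) = 0$; a free intercept is available as a
diagnostic. Points at or above the saturation temperature (default
240 °C absolute, where micro-bubble formation and similar surface
phenomena break the linear regime) are excluded from the fit and
reported, never silently dropped; predicted surface temperatures beyond
the cap are returned but flagged as extrapolations.

## Footprint image analysis

`analyze_frame()` composes four steps, each exposed on its own:

1. **Centroid localisation** on the reflection channel (fluorescence
   fallback with a warning): intensity-weighted centroid after
   subtracting the median and clipping negatives; sub-pixel accurate to
   better than 0.05 px on symmetric spots. Pixel centers sit at integer
   coordinates, origin at the top-left pixel center; radii are measured
   center-to-center. This convention must be fixed for sub-pixel
   threshold crossings to be meaningful.
2. **Rotational averaging**: mean intensity over annuli (default width
   one pixel), the 0 to 2π average at every distance, clipped at the
   image boundary.
3. **Background**: the mean over a user rectangle, or by default over
   an annulus at 75--95% of the field half-width -- several micrometres
   outside any footprint that fits the field, but fully inside the
   image. (An annulus strictly outside the image diagonal would contain
   no pixels, so "far away" is bounded by the field.) A user rectangle
   that intrudes within twice the expected footprint radius of the
   center is rejected.
4. **Threshold crossing**: the melted-region maximum is the profile
   maximum within 2 µm of the center (averaging before taking the
   maximum makes this robust to single-pixel noise);
   $Tr = \text{background} + 0.5\,(\text{max} - \text{background})$;
   $D_m$ is the *first* outward crossing below $Tr$, linearly
   interpolated between bin centers. First rather than last crossing is
   robust to bright debris in the periphery.

The 50% rule is affine-equivariant, so $D_m$ is exactly invariant under
any positive affine rescaling of the frame, and invariant to within
half a pixel under rotation about the particle center -- both are
tested properties.

No PSF deconvolution is attempted. Footprints smaller than twice the
PSF width are flagged `diffraction_limited` instead: in that regime the
measured footprint cannot shrink below the PSF, so $D_m$ (and hence the
inferred surface temperature) is overestimated, with a bias that grows
as the true footprint shrinks. For well-resolved footprints the bias of
the 50% rule changes sign and becomes slightly negative (a fraction of
a pixel; the rotationally averaged edge of a *convex* boundary falls
just below half-maximum at the true radius), which is why the
diffraction flag, not a correction, is reported.

## PET treatment-response statistic

Ablated and necrotic tissue stops accumulating FDG, but an effective
treatment may only affect a subvolume, leaving ROI mean and maximum
%ID/g nearly unchanged. The response statistic is therefore the *low
uptake volume*: with per-scan ROI mean $\mu$ and sample (n−1) standard
deviation $\sigma$,

$$V_{low} = \#\{\text{ROI voxels with uptake} < \mu - 1.5\,\sigma\}
  \times V_{voxel},$$

and follow-ups are normalised per animal,
$V_{low}(t)/V_{low}(\text{baseline})$. The threshold is strictly
"below" (ties excluded), the SD is the sample SD over the scan's own
ROI (both choices configurable; the per-scan reading follows the
methods wording), and voxel volume comes from the NIfTI header with no
partial-volume correction.

Because the threshold is affine-equivariant, $V_{low}$ is *exactly*
invariant under positive affine transforms of the uptake -- calibration
rescalings cannot move it. On a pure Gaussian ROI the expected fraction
below threshold is $\Phi(-1.5) = 6.68\%$, a closed-form anchor the
phantom tests verify to binomial accuracy. One behaviour worth knowing:
since the threshold adapts to the scan's own $\mu$ and $\sigma$, a
*small* cold lesion inflates $\sigma$, depresses the threshold and can
transiently *reduce* $V_{low}$ relative to a lesion-free scan; the
statistic is monotone in lesion volume once the lesion dominates the
tail. Group summaries (`cohort_summary()`) are means ± SD only --
descriptive, no hypothesis testing.

## Synthetic generators and what they do (not) show

All generators take an explicit seed, restore the caller's RNG state,
and return their ground truth alongside the data.

* `make_footprint_frame()`: hard disk of fluid-phase intensity on a gel
  background, rendered at 4× supersampling, blurred with the analytic
  Gaussian transfer function in Fourier space, box-averaged to the
  pixel grid; Gaussian or Poisson noise; reflection channel a blurred
  point emitter. Default PSF $\sigma = 0.073$ µm
  ($0.21\,\lambda/\mathrm{NA}$ at 488 nm, NA 1.4), pixel 0.08 µm. A
  zero-width PSF renders an exact two-level disk, which pins the
  geometry conventions.
* `make_footprint_series()` inverts the heating relation at the melting
  boundary, $D_m = C\,I/(T_m - T_{ambient})$, so the full
  image-analysis + thermometry chain can be round-tripped against a
  known $C$ (1% noiseless, 5% at SNR 10 over 100 frames).
* `make_pet_phantom()`: ellipsoidal tumor (defaults: semi-axes 5.5,
  5.5, 5.6 mm, about 700 mm³, on a 0.29 × 0.29 × 0.79 mm voxel grid
  matching the scanner geometry), bulk uptake Normal(6, 1) %ID/g
  truncated at zero (the truncation is negligible for
  $\mu/\sigma \ge 4$, kept so by default), plus spherical necrotic
  core and cold lesion at fixed uptakes. `make_treatment_pair()`
  scripts a treated animal: 50 mm³ core at baseline, plus a disjoint
  100 mm³ ablation lesion at day 0, so the expected relative change is
  3.0 (recovered within the lesion-voxelisation tolerance; the small
  residual bulk tail at baseline biases the ratio a few percent low).
* `make_heating_series()`: $\Delta T_P = C\,I/R + \varepsilon$, capped
  at the saturation temperature.

What passing these tests does *not* show: the frames have ideal
Gaussian PSFs, no bleaching, flat illumination and a single particle;
the phantoms have white Gaussian texture rather than reconstructed-PET
noise correlations, and no scanner PSF or partial-volume blur. The
generators validate the *estimators*, not the microscope or the
scanner.

## Problem sizes

The shipped test-suite and acceptance-script sizes are chosen to be
informative at interactive timescales: spectra on the 701-point default
grid, 160² px frames (100 of them for the noisy round-trip), 400
simulated heating series for the slope-CI calibration, and ~55k-voxel
phantoms (~10k ROI voxels), for a full run in about two minutes. All
scale parameters are arguments, so heavier sizes are one call away.

## Design choices on genuinely open points

* *Which spectral channel corresponds to published "absorption"
  spectra*: UV-vis spectrophotometry measures extinction, so extinction
  is the comparison channel for peak positions; both channels are
  exposed and `peak_wavelength()` takes the channel explicitly.
* *Extent of the melted-region ROI*: taken as a 2 µm radius around the
  particle, consistent with averaging-first ordering; the 50% level is
  measured between that ROI's profile maximum and the background.
* *Per-scan vs pooled SD for the PET threshold*: per-scan, matching the
  "in all PET images" reading; configurable.
* *First vs last threshold crossing*: first, for robustness to
  peripheral debris.
* *In vivo endpoints*: individual-animal uptake trajectories and group
  p-values are not reproducible from published summary data; the
  platform's deliverable at that level is the particle *ranking*
  (nanoshell above equal-size solid sphere above 80 nm sphere at
  807 nm), which `run_benchmark()` reproduces from theory alone.
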