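---
title: "Force-spectroscopy kinetics and AFM volumetrics: models, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-spectroscopy kinetics and AFM volumetrics: models, design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bondkin)
```

# The inference problem

Dynamic force spectroscopy measures how the rupture force of a single
receptor–ligand bond depends on how fast it is loaded. Under the Bell
ansatz, force tilts the unbinding energy landscape so the off-rate grows
as $k(F) = k_{\mathrm{off}} e^{F x_\beta / k_B T}$; under a constant
force ramp $F = r_f t$ the most probable rupture force is

$$F^* = \frac{k_B T}{x_\beta} \ln \frac{r_f x_\beta}{k_{\mathrm{off}} k_B T},$$

floored at zero (a negative most-probable force is unphysical; it simply
means the bond usually decays thermally before force builds up).
`bondkin` estimates $(k_{\mathrm{off}}, x_\beta)$ from the linear
dependence of peak rupture force on $\ln r_f$, then uses the Williams
Markov model of $N_B$ identical load-sharing bonds, both to predict the
force branch of bivalent ruptures with no additional parameters and to
correct the dissociation rate for simultaneous two-bond rupture
($k_{\mathrm{off},2} = \tfrac{2}{3} k_{\mathrm{off}}$).

Everything upstream of those fits — event detection, noise estimation,
density construction, loading-rate segmentation — follows the
experimental convention of building "experimental pdfs": each measured
value contributes a unit-area Gaussian whose width is that measurement's
own error, so no histogram binning is involved, and the dominant peak of
each loading-rate segment is fitted with a single Gaussian whose mean
and SD feed the weighted Bell–Evans regression.

# Tunable parameters that matter

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| `kBT` | pN·nm | 4.114 | room temperature (298.15 K) |
| `min_drop_sigma` | — | 4 | detection threshold in noise SDs; windowed means make the per-curve false-positive rate negligible while keeping >98% sensitivity at 5 pN noise |
| `max_drop_width` | nm | 2 | a rupture is an essentially instantaneous force drop; wider "drops" are baseline wander |
| `slope_window` | nm | 10 | pre-rupture window for the effective spring constant (loading rate = slope × speed) |
| baseline window | trace fraction | 0.2 | trailing post-detachment segment for noise estimation (linear detrend first) |
| segment width | log10(pN/s) | 0.5 | two segments per decade, boundaries at multiples of 0.5; segments under 20 events are dropped |
| pdf `grid_step` | value units | min(σ)/4 | resolves the narrowest kernel |
| volume kernel | nm³ | 4 | measurement error of AFM particle volumes |
| `min_pixels` | px | 4 | smallest credible particle footprint |
| `c_eff` radius | nm | tether + molecule length | hemispherical reach volume of the tethered ligand |

Representative loading rate of a segment is the **geometric mean** of
its members' rates: the Bell–Evans abscissa is $\ln r_f$, so the
log-domain centroid is the natural regressor. Weights in the regression
are $1/\mathrm{peak\_sd}^2$. Errors on rates are carried in **log10
decades** throughout, matching the mantissa ± exponent convention of
kinetic tables; `compute_affinity()` adds them in quadrature, which a
Monte-Carlo oracle in the test suite confirms to within 5%.

# The force-curve simulator

The generator emulates the statistical structure the inference stages
assume, with exact ground truth per curve:

* **Binding over contact time.** A first bond forms with
  $P = A(1 - e^{-(t_c - t_0)/\tau})$ (zero at or below the lag $t_0$);
  conditional on it, a second bond forms with the same functional form
  and its own amplitude and timescale ($t_0 = 0$ — any lag is absorbed
  by the first bond's).
* **Tether mechanics.** Worm-like chain (interpolation formula),
  persistence length 0.38 nm and contour length 8 nm by default (a
  typical short PEG crosslinker; these are declared assumptions, not
  measured values), in series with the cantilever (10 pN/nm) and a soft
  surface compliance (5 pN/nm) standing in for membrane deformation.
  The series stiffness at rupture is the local slope, so loading rate =
  slope × speed is recoverable from the trace exactly as an
  experimentalist would.
* **Rupture sampling.** Single bonds are drawn by exact inverse-CDF
  sampling of the Bell first-passage density under a constant ramp. Two
  bonds follow a two-state Markov cascade with equal load sharing: pair
  hazard $2 k_{\mathrm{off}} e^{F x_\beta / 2 k_B T}$, survivor hazard
  $k_{\mathrm{off}} e^{F x_\beta / k_B T}$, both inverted in closed form
  (no time discretization). The constant ramp rate per curve is chosen
  self-consistently by fixed-point iteration of
  $F^* = F^*(k_{\mathrm{eff}}(F^*) \cdot v)$ on the series elasticity.
* **Sequential vs simultaneous.** Two failures closer than a
  resolution threshold (default 0.5 nm of tip travel) merge into one
  apparent step, mimicking the instrument's inability to resolve
  near-coincident drops. Sequentially failing pairs are rendered as a
  partial drop to the survivor's load share followed by reloading along
  the same elasticity.
* **Noise and determinism.** White Gaussian force noise with a per-curve
  SD drawn from a configurable range; no 1/f component (no noise
  spectrum is specified for the emulated instrument). One scenario seed;
  per-curve substreams derive from it by counter, so a curve's content
  does not depend on how many conditions precede it.

What the generator does **not** emulate: approach-phase contact
mechanics, cell viscoelasticity, thermal cantilever dynamics, multiple
tethers, rebinding during retraction, drift other than linear baseline
slope. Passing the recovery tests therefore shows the inference chain is
correct and well calibrated for data obeying its own assumptions — not
that those assumptions hold for any particular instrument.

# AFM volumetrics

The image chain reimplements the standard manual workflow: three-point
plane leveling with patch averaging (so noise at an anchor does not tilt
the plane), Gaussian smoothing (separable kernel, reflective borders),
masking at 50% of the **raw** image's maximum height applied to the
leveled, smoothed image, 8-connected labeling, and per-particle volume
integration. Two wordings in that workflow are ambiguous and were
resolved as follows:

* "50% of the height" is read as 0.5 × maximum height (not 0.5 × height
  range). With a leveled background near zero the two coincide; the
  threshold is also directly overridable.
* The mask at half height contains only ~50% of a Gaussian-profile
  particle's integral, so integrating strictly over mask pixels would
  systematically halve volumes. The integration footprint is therefore
  the mask grown by 1.5× the core's equivalent radius (minimum 3 px),
  with the local background taken as the median of a ring outside the
  grown footprint; on synthetic Gaussian particles this recovers
  integrated volumes to within 10%.

Border-touching particles are flagged and excluded from statistics by
default. Oligomeric states are assigned by fitting the volume pdf with a
multi-Gaussian (the number of states counted from pdf local maxima above
a prominence floor, overridable), placing boundaries at midpoints
between adjacent fitted peaks, and classifying each particle by the
segment containing its volume; adjacent peaks closer than one kernel SD
are merged with a warning.

The synthetic image generator places Gaussian-profile particles of
specified integrated volume at constant peak height (default 2.5 nm) on
a tilted, noisy plane: protein oligomers grow laterally rather than
vertically, which is also why a half-maximum threshold does not swallow
monomers. Defaults (0.5 nm pixels, 0.05 nm noise, ~0.3 nm of tilt
across the field) reflect typical high-speed AFM imaging of single
proteins.

# Numerical choices

* `williams_force()` inverts the Williams relation by bracketed Brent
  root-finding with geometric bracket expansion; the relation is
  strictly monotone, so the root is unique and converged to better than
  $10^{-8}$ relative in rate.
* pdf grids extend 6 kernel SDs beyond the data (truncated tail mass
  ~$10^{-9}$), so the trapezoidal integral is 1 within $10^{-6}$ without
  renormalization and the density equals the plain Gaussian sum exactly.
* All nonlinear fits use Levenberg–Marquardt (`minpack.lm::nls.lm`) with
  box bounds; mixture fits are initialized at the largest local density
  maxima (surplus components are seeded offset from the tallest peak and
  flagged when their fitted weight falls below 0.02); the binding-
  kinetics fit retries over a coarse τ grid before reporting failure.
* Degenerate inputs fail loudly and specifically: constant binding
  probabilities (τ unidentifiable), fewer than 3 segments, fewer than 4
  contact times, collinear leveling anchors, empty masks, non-positive
  rates.
* The second-bond $P_2(t_c)$ fit fixes $t_0 = 0$ by default; the lag is
  a property of establishing the first contact.
* The competitive-assay comparison uses a two-sided Welch test on
  per-cell binding probabilities (the robust default when the underlying
  test is unspecified); it is configurable.

# Validation problem sizes

The acceptance tests exercise the full chain at sizes chosen to give
stable statistics on one CPU in minutes: parameter recovery and the
two-bond overlay use 6 pulling speeds × 600 curves (noise 5 pN, binding
probability 0.3, 30% bivalent where relevant); contact-time kinetics use
8 contact times × 300 curves × 100 replicates; the volume pipeline uses
8 images × 50 particles of a 27/54 nm³ monomer/dimer mixture. The
recovery targets are ±0.3 decades on $\log_{10} k_{\mathrm{off}}$ and
±20% on $x_\beta$. For the contact-time experiment the
Cramér–Rao bound on $\mathrm{se}(\hat\tau)$ at these sample sizes is
itself ≈10% of τ, so per-replicate estimates at the 10% level are
boundary cases rather than guaranteed outcomes — a fundamental
information limit of binomial sampling at 300 curves per point, not an
estimator deficiency; collapsing τ uncertainty below that requires more
curves per contact time.

# Known limitations

* Only $N_B \le 2$ is sampled by the simulator cascade (the analytic
  Williams functions accept any $N_B$); heterogeneous bonds,
  catch-bond behavior and rebinding are out of scope.
* The Bell–Evans peak procedure inherits a small downward bias of the
  pdf peak position when measurement noise is comparable to the
  intrinsic force spread (the skewed rupture distribution convolved
  with noise shifts its mode); at 5 pN noise this is ~1–3 pN, well
  inside the recovery tolerances, and it is a property of the published
  procedure itself rather than of this implementation.
* TIFF height maps are stored normalized with a JSON calibration
  sidecar (32-bit float TIFF round trips exactly through the pair);
  the plain-text matrix format is self-contained and lossless.
* The command-line surface is the R API plus `run_pipeline()` on a YAML
  configuration; this package's users drive it from R scripts, so no
  separate shell binary is shipped.
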