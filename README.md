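# bondkin

Single-molecule force spectroscopy (SMFS) kinetics and AFM particle
volumetrics in R.

`bondkin` is for biophysicists who probe receptor–ligand bonds by pulling
on them: an AFM cantilever, functionalized with a ligand through a
flexible PEG tether, is repeatedly brought into contact with a cell or
surface carrying the receptor, and each retract trace may show one or
more unbinding events. From thousands of such force–distance cycles the
package extracts the full kinetic fingerprint of the bond — dissociation
rate, energy-barrier width, association rates, affinity, lifetime — and,
from high-speed AFM height images, the oligomeric state distribution of
the receptor itself. A Monte-Carlo force-curve simulator and a synthetic
image generator with exact ground truth make every inference stage
testable without instrument data.

## Models

**Bell–Evans.** A slip bond loaded at rate $r_f$ (pN/s) ruptures most
probably at

$$F^* = \frac{k_B T}{x_\beta}\,
\ln\!\frac{r_f\, x_\beta}{k_{\mathrm{off}}\, k_B T},$$

so $F^*$ grows linearly with $\ln r_f$; a weighted fit of peak rupture
forces against log loading rate yields the zero-force dissociation rate
$k_{\mathrm{off}}$ and barrier width $x_\beta$ (`fit_bell_evans()`).

**Williams parallel bonds.** $N_B$ identical, uncorrelated bonds sharing
the load obey

$$r_f = k_{\mathrm{off}} \frac{k_B T}{x_\beta}
\left[\sum_{l=1}^{N_B} \frac{1}{l^2}
e^{-F^* x_\beta/(l\,k_B T)}\right]^{-1},
\qquad
k_{\mathrm{off},N_B} = k_{\mathrm{off}}
\left[\sum_{l=1}^{N_B} \frac{1}{l}\right]^{-1}.$$

The first relation predicts the force of bivalent ruptures with zero free
parameters once the single-bond fit is known
(`predict_double_bond_overlay()`); the second gives the effective
dissociation rate of simultaneous two-bond rupture, $\tfrac{2}{3}
k_{\mathrm{off}}$ for $N_B = 2$ (`koff_parallel()`).

**Binding kinetics.** The probability that a contact of duration $t_c$
forms a bond follows pseudo-first-order kinetics,
$P = A\,(1 - e^{-(t_c - t_0)/\tau})$; the interaction time $\tau$
converts to a bimolecular on-rate through the effective concentration of
one tethered ligand in a hemispherical reach volume,
$k_{\mathrm{on}} = (\tau\, c_{\mathrm{eff}})^{-1}$ with
$c_{\mathrm{eff}} = N/(N_A \cdot \tfrac{2}{3}\pi r^3)$; later bonds form
at $k_2 = 1/\tau_2$. Affinities follow as
$K_D = k_{\mathrm{off}}/k_{\mathrm{on}}$ with errors propagated in log10
decades, and lifetimes as $\tau = 1/k_{\mathrm{off}}$.

**Experimental pdfs.** Distributions of rupture forces (and particle
volumes) are built as sums of unit-area Gaussians, one per measurement,
each with its own measurement error as width (`build_pdf()`) — a
continuous histogram free of binning artefacts — and decomposed by
multi-Gaussian least squares (`fit_multi_gaussian()`).

**AFM volumetrics.** Height images are plane-leveled on three anchor
patches, Gaussian-smoothed, thresholded at half the raw maximum height,
and each 8-connected particle integrated to a volume; the volume pdf is
split into oligomeric states at midpoints between fitted peaks
(`analyze_afm_image()`).

## Worked example

Simulate a six-speed pulling experiment (0.75–12 µm/s, 120 curves per
speed, bond with $k_{\mathrm{off}} = 0.03\ \mathrm{s}^{-1}$,
$x_\beta = 0.5$ nm), detect ruptures, and refit the bond parameters:

```r
library(bondkin)
cfg <- list(seed = 5, scenario = list(
  pulling_speeds = c(0.75, 1.5, 3, 6, 9, 12), curves_per_condition = 120,
  binding_A = 0.6, binding_t0 = 0, binding_tau = 0.05, contact_times = 1,
  bond = list(k_off = 0.03, x_beta = 0.5)))
res <- run_pipeline(cfg)
res$fit
#> Bell-Evans fit (4 segments): k_off = 1.8e-02 +/- 0.15 1/s, x_beta = 0.523 +/- 0.017 nm
res$binding$fraction
#> 0.629
```

The fit recovers the simulated barrier width within ~5%; the
dissociation-rate estimate sits 0.22 decades below the simulated
$3\times10^{-2}\ \mathrm{s}^{-1}$ (about 1.5 fitted log-scale standard
errors — the intercept of a four-segment semi-log fit is the least
constrained quantity, and larger datasets tighten it, as the acceptance
tests show at 600 curves per speed). The detected binding probability
0.629 matches the scenario's binding probability of 0.6.

Published rate constants for the CD40 system are bundled as inputs for
the derived-quantity machinery:

```r
summarize_rates(cd40_reference_rates())
#> Kinetic rate table
#> hIgG1    k_off 4.1e-02 +/- 0.26  k_off,2 2.7e-02 +/- 0.26  k_on 2.6e+04 +/- 0.09  k_2 5.5e+00 +/- 0.17  K_D 1.6e-06 +/- 0.28  K_D,2 1.1e-06 +/- 0.28
#> hCD40L   k_off 3.5e-01 +/- 0.1   k_off,2 2.3e-01 +/- 0.1   k_on 1.6e+05 +/- 0.07  k_2 1.7e+01 +/- 0.09  K_D 2.2e-06 +/- 0.12  K_D,2 1.5e-06 +/- 0.12
```

(k_off,2 here is recomputed as $\tfrac{2}{3} k_{\mathrm{off}}$, K_D as
k_off/k_on; both agree with the published two-significant-figure values.)

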