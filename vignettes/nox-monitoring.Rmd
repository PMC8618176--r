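---
title: "Monitoring nitrification from UV-Vis spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring nitrification from UV-Vis spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NOxMonitor)
```

## The measurement model

A blank-corrected UV absorbance spectrum of chloraminated drinking water in
the 200–300 nm window is, to a good approximation, the Beer–Lambert sum of
three absorbers over the optical path $L$ (here a 10 cm cell):

$$A(\lambda) = L\,\big[\varepsilon_{\mathrm{NH_2Cl}}(\lambda)\,c_{\mathrm{NH_2Cl}}
 + \varepsilon_{\mathrm{NO_x}}(\lambda)\,c_{\mathrm{NO_x}}
 + \varepsilon_{\mathrm{NOM}}(\lambda)\,c_{\mathrm{DOC}}\big].$$

Free ammonia absorbs negligibly at drinking-water concentrations and NOM
(tracked as dissolved organic carbon) changes much more slowly than the
disinfectant residual, so over a monitoring window of weeks the *change* of
the spectrum against its baseline $S_0$ is driven by two opposing processes:
monochloramine decay pulls the spectrum down, with the largest offset at the
245 nm absorption peak, while nitrite/nitrate production pushes it up below
about 230 nm. All spectra in a series are assumed blank-corrected (net
absorbance against ultrapure water) and acquired with one pathlength;
operations refuse to mix pathlengths rather than silently rescale, because a
different cell implies a different calibration, not a scalar correction.

## Decay compensation anchored at 245 nm

Nitrate and nitrite have no meaningful absorbance at 245 nm — that is what
makes the offset there, $\Delta_{245} = S_0(245) - S_t(245)$, a clean proxy
for decay. In ultrapure water the offsets between any two monochloramine
concentrations at different wavelengths are proportional, so an ordinary
least-squares line per wavelength,

$$\Delta_i = a_i\,\Delta_{245} + b_i, \qquad i = 200, 200.5, \dots, 244.5\ \mathrm{nm},$$

fitted from **all pairwise combinations** of a calibration series (default:
10 levels spanning 0.2–5 mg L⁻¹, giving $\binom{10}{2} = 45$ records,
oriented higher-minus-lower so anchors are nonnegative) captures the band
shape. On exact Beer–Lambert data the slopes equal the absorptivity ratio
$\varepsilon(\lambda_i)/\varepsilon(245)$ and the intercepts vanish; the
intercepts are nevertheless *fitted*, not forced to zero, so that deviations
in real data surface in the per-wavelength diagnostics (squared Pearson
correlation and RMSE) rather than being hidden. A configuration switch
restricts the records to baseline-referenced pairs, but all-pairs is the
default because it uses the full information of the series.

Applying the model: the decay-only estimate is
$\hat S(\lambda_i) = S_0(\lambda_i) - \hat\Delta_i$ on the modelled grid and
$S_0(245) - \Delta_{245}$ at the anchor. A **negative** sample anchor means
absorbance *rose* at 245 nm, which decay cannot produce; the pipeline warns
and applies zero compensation rather than extrapolating the lines into a
regime they were never fitted for. Beyond 245 nm the default rule mirrors
the modelled offsets about the anchor ($\hat\Delta(245+x)=\hat\Delta(245-x)$,
reasonable because the monochloramine band is symmetric; zero past the
mirror's reach), with a plain zero-compensation alternative; the choice is
cosmetic for quantification, which only reads 200–245 nm. The isolated NOx
spectrum $S_t - \hat S$ is left unclipped — noise legitimately produces small
negative values, and clipping would bias the regression input; a
clip-at-zero variant exists for display only.

## Quantification by support-vector regression

Features are the absorbances at every 0.5 nm point in 200–245 nm (91
features); the label is the combined NOx-N concentration. Features *and*
labels are min-max scaled to $[-1, +1]$ (per feature, from the training set,
fitted once before cross-validation); predictions are inverse-transformed
and clipped at 0 mg-N L⁻¹. The regression is $\varepsilon$-insensitive SVR
with an RBF kernel (libsvm via e1071), tuned by exhaustive grid search over
$C \in \{0.1, 1, 10, 100, 1000\}$ and
$\gamma \in \{0.001, 0.01, 0.1, 1\}$ with seeded 10-fold cross-validation
(shuffled assignment, no stratification — labels are continuous).

Two deliberate choices:

* **Selection by pooled validation RMSE, not R².** The R² used throughout is
  the squared Pearson correlation, which is invariant under any affine
  transform of the predictions (an anticorrelated prediction scores 1). It
  is reported because it is the field's customary diagnostic, but it cannot
  drive model selection safely.
* **$\varepsilon = 0.001$ in scaled label units** (≈ 0.0012 mg-N L⁻¹ with the
  default 0–2.4 mg-N L⁻¹ label range). No published value exists for this
  margin; it is exposed in the configuration. Smaller values cost support
  vectors, larger ones cap the attainable precision.

Training standards are Cartesian nitrite × nitrate mixtures over
$\{0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.3, 0.6, 0.9, 1.2\}$ mg-N L⁻¹ each
(100 samples, combined labels up to 2.4 mg-N L⁻¹ — the method's working
ceiling; predictions beyond it are flagged as extrapolated). Predictions of
a zero spectrum sit at the training noise floor, and over an unseen 5×5 grid
of mixtures inside the training hull the noise-free recovery error stays
within ±0.01 mg-N L⁻¹.

A **local calibration** (least-squares line from raw predictions to
laboratory NOx-N values) corrects site-specific bias; it needs at least two
distinct points and is applied after prediction. No correction is attempted
for lab/spectrum acquisition-time mismatch — with no model of the intervening
kinetics any such adjustment would be guesswork.

## The synthetic generator

The generator exists so that every downstream stage can be validated against
exact ground truth. It emulates:

* **Component bands.** Gaussian bands for the chemical species: monochloramine
  centred at 245 nm ($\sigma = 20$ nm, so the 200 nm shoulder keeps a few
  percent of peak absorptivity, as the quality of per-wavelength fits at the
  far end of the window implies for the real band), peak absorptivity
  0.0086 AU/(mg L⁻¹)/cm (from a molar absorptivity of ≈445 M⁻¹cm⁻¹);
  nitrite at 210 nm ($\sigma = 8.5$, 0.20 AU/(mg-N L⁻¹)/cm, secondary band
  at 355 nm); nitrate at 205 nm (right-skewed, $\sigma_L = 7$,
  $\sigma_R = 9.5$, 0.28 AU/(mg-N L⁻¹)/cm — higher than nitrite per unit
  nitrogen, secondary band at 302 nm); NOM as a strictly decreasing
  exponential continuum $0.045\,e^{-0.015(\lambda-200)}$ per mg-C L⁻¹ per cm.
  Reported secondary-peak assignments for nitrite/nitrate conflict in the
  literature between (355, 302) and (302, 355); the generator uses
  nitrite → 355 nm, nitrate → 302 nm.
* **Compact band support.** The nitrite/nitrate bands are pedestal-subtracted
  Gaussians truncated at $\pm 4\sigma$, so their absorptivity is exactly zero
  at and beyond 244 nm. This is deliberate fidelity, not convenience: the
  anchor wavelength works *because* these species do not absorb there, and an
  unbounded tail — however small in AU — violates that premise while its
  min-max-scaled feature image can become arbitrarily large on noise-free
  data (a microscopic dynamic range is stretched to the full $[-1,1]$
  interval).
* **Saturation.** Strict Beer–Lambert scaling cannot move an argmax, yet
  concentrated nitrate solutions show an apparent red-shifted peak. The
  generator reproduces this with an optional detector ceiling: hard clipping
  turns the right-skewed nitrate band into a plateau whose midpoint (what
  `peakWavelength()` reports for a flat top) lies above 205 nm.
* **Decay/nitrification kinetics.** First-order monochloramine decay
  ($c_0 e^{-kt}$); ammonia-N released at a fixed stoichiometric yield per mg
  NH₂Cl decayed (default 0.25 mg-N/mg — a configurable placeholder, no
  published value exists); after an onset lag, the available ammonia-N
  converts to NOx-N along $\tanh(rt/2)$ (logistic in shape, monotone, zero at
  onset), split between nitrite and nitrate by a configurable fraction
  (default 0.5). Nitrogen is conserved to 1e-9 by construction. DOC may
  drift linearly (≤ 0.2 mg-C L⁻¹ over the horizon is realistic for a
  multi-week study); the validation scenarios use zero drift because NOM
  drift is *uncompensated* by the method — it is a known bias source, and the
  stated ±0.01 mg-N L⁻¹ precision is only meaningful under the idealized
  noise-free conditions.
* **Noise.** Additive Gaussian instrument noise, default 0.001 AU where a
  noisy series is wanted, seeded and bit-reproducible.

What the generator does **not** emulate — and hence what passing tests do not
establish about field data: particle/turbidity absorbance (real samples are
0.45 µm filtered; no chemometric particle compensation), dichloramine and
other minor chlorine species, pH effects (reported insignificant between
pH 7 and 9), wavelength-dependent or drifting instrument noise, internal
reactions between absorbers, and NOM composition changes that alter its
spectral shape rather than its amount. Real monochloramine and NOx band
shapes are also only approximated; absolute absorptivities are free
parameters chosen for realistic AU magnitudes, since the pipeline's claims
are about relative changes, not absolute spectral reproduction.

## Numerical choices and degenerate inputs

* Wavelength comparisons use a 1e-6 nm tolerance; grids are uniform and the
  default analysis grid is 200–300 nm at 0.5 nm (201 points), with the
  compensation fitted on 200–244.5 nm (90 points).
* Grid alignment is linear interpolation, exact on affine spectra and a
  pass-through on matching grids; requests outside the recorded span are
  errors, never extrapolation.
* Degenerate calibrations fail loudly: fewer than 3 spectra (or pair
  records) is an insufficient-calibration error; all-equal anchors a rank
  deficiency; a constant vector makes the squared-correlation R² undefined
  (NaN with a warning, never silently 0 or 1).
* Grid-search ties are broken toward smaller $C$, then smaller $\gamma$ —
  the least flexible model among equals.
* Constant features scale to 0 (they carry no information); unseen feature
  values map affinely outside $[-1, 1]$ rather than being clipped.
* Every source of randomness (noise, fold shuffles) is seeded; identical
  configurations rerun byte-identically, and output files embed the seed and
  a hash of the configuration.

## Problem sizes

The shipped validation uses the sizes natural to the method: a 10-level
calibration series (45 pair records, 90 fitted wavelengths), a 100-sample
training set of 91-feature spectra with a 20-tuple parameter grid under
10-fold cross-validation, and 8-timestamp weekly monitoring series. A full
pipeline run — calibration, grid search, training, monitoring — completes in
a few seconds on one core.

## Known limitations

* The compensation model transfers ultrapure-water monochloramine behaviour
  to drinking water by assumption; matrix effects show up only as degraded
  diagnostics, not corrected estimates.
* Estimates are *relative* to the series baseline. The baseline's own NOx
  content must come from elsewhere (an optional configuration field adds it
  to reported totals), and long-running deployments must re-baseline as the
  incoming water changes.
* Above 2.4 mg-N L⁻¹ combined NOx-N the regression extrapolates (flagged);
  a shorter-pathlength cell and a recalibration, not a rescale, is the
  correct response to persistently high concentrations.
* The 0.05 mg-N L⁻¹ alert threshold is a screening heuristic on *combined*
  NOx (the underlying guideline concerns nitrite); alerts mean "investigate",
  not "nitrification confirmed".
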