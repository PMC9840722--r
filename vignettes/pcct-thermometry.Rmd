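---
title: "Photon-counting CT thermometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon-counting CT thermometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Thermal ablation destroys tumours by focal heating, and guiding it well
requires volumetric thermometry. CT can serve because heating expands a
material, lowers its density, and therefore lowers its X-ray linear
attenuation coefficient (LAC, $\mu$, here always in mm$^{-1}$). In
Hounsfield units the first-order model is

$$\Delta CT(T) \approx -\left[1000 + CT(T_0)\right]\,\alpha\,\Delta T,$$

with $T_0$ a baseline temperature and $\alpha$ the volumetric thermal
expansion coefficient (`predict_delta_ct()`). The *thermal sensitivity* —
attenuation change per °C — is approximately constant over the
therapeutically relevant 30–90 °C but varies strongly between tissues,
which is why classical CT thermometry needs per-material calibration.

A photon-counting detector counts photons above programmable energy
thresholds, so a single exposure yields attenuation in several energy
bins. Two paired acquisitions (thresholds 8/45 keV and 33/60 keV) are
subtracted into the four bins 8–33, 33–45, 45–60 and 60–100 keV
(`counts_to_bins()`). Spectral attenuation enables *material
decomposition*: the LAC of a volumetric mixture is the
volume-fraction-weighted sum of its components per bin,

$$\mu(E_k) = \sum_i V_i\,\mu_i(E_k), \qquad \sum_i V_i = 1 .$$

`decompose_lac()` solves this with all four bins in least squares while
enforcing the sum constraint exactly (a small KKT system). Fractions
outside $[0,1]$ are reported raw with a flag so the residual norm stays
diagnostic for materials outside the span of the bases.

If each base were linear in temperature,
$\mu_i(T) \approx \alpha_i (T - T_0) + \mu_i(T_0)$, a mixture would obey
$\mu(T) = \alpha'(T-T_0) + \beta'$ with
$\alpha' = \sum V_i \alpha_i$, $\beta' = \sum V_i \mu_i(T_0)$
(`linear_mixture_thermal_model()`). Thermal expansion is governed by
intermolecular bonding, so sensitivity is *not* linear in composition:
for CaCl$_2$ solutions it follows a quadratic-or-higher trend in
concentration. That failure of the linear model is the motivation for a
learned regressor.

## Extracting spectral LACs from projections

The measurement is deliberately reconstruction-free. A square-section
liquid phantom is imaged empty and filled; one detector row (the line of
interest, LOI, default row 200) is analysed per frame:

1. **Unstable-pixel removal.** Columns deviating from the profile mean by
   more than 3 SD are masked (`clean_unstable_pixels()`), in a single
   pass; a constant profile has zero SD and masks nothing. In the full
   chain the statistics are computed on the *empty* (flat) profile, where
   the expected signal is constant, and the mask is applied to both
   frames — on the filled profile the phantom's own shadow structure
   would otherwise be mistaken for instability.
2. **Profile difference.** $\Delta p(x) = \ln\!\big(I_e(x)/I_f(x)\big)$
   (`profile_difference()`); any attenuation common to both acquisitions
   — the phantom enclosure — cancels in the ratio.
3. **Denoising.** A 5-pixel sliding average then a 7-pixel median filter
   (`denoise_profile()`), windows truncated at the ends of the valid run.
   The order matters: a solitary spike reaching this stage is first
   spread by the mean window and only bounded (not removed) by the
   median; full removal is the job of the preceding 3-SD mask.
4. **Weak-perspective integration.** The X-ray source is a point, so rays
   through the phantom diverge. Dividing the profile area by the
   geometric magnification $M$ (source–detector over source–centre
   distance; 342.5/278.5 ≈ 1.23 at the default geometry) approximates
   the parallel-beam line-integral area, and

   $$\mu = \frac{p}{L^2} \sum_x \frac{\Delta p(x)}{M}$$

   with $p$ the pixel pitch (0.055 mm) and $L$ the phantom side, i.e.
   (demagnified profile area) ÷ (phantom cross-section area) = mean LAC
   (`integrate_lac()`, trapezoidal over columns, masked columns filled by
   linear interpolation). The weak-perspective error against a true
   parallel beam is below 3% at the default distances; the test suite
   verifies this against a brute-force ray-marching integrator.
5. **Variance.** The whole chain runs on 10 adjacent LOIs
   (`lac_with_variance()`); the unbiased inter-LOI variance quantifies
   measurement spread per bin.

**Geometry notes.** The printed setup values are mutually inconsistent:
a 254 mm phantom cannot cast a 1.23× magnified shadow onto a
70.4 mm-wide detector. `phantom_geometry()` keeps the printed defaults
(all fields overridable); simulations that need a self-consistent scene
use `consistent_geometry()`, which keeps the distances and pitch but
uses a 25.41 mm side. That value is exactly 462 pixel pitches, so in the
parallel-beam configuration the phantom edges land on pixel boundaries
and the discrete identity $\sum_x \mathrm{chord}(x)\,p = L^2$ holds to
machine precision — the parallel-beam extraction check is then a pure
geometric identity, not a tolerance compromise. The forward simulator
(`simulate_projection_pair()`) treats each detector row as a fan
(the LOI analysis is one-dimensional); chords through the square are
computed by analytic slab intersection, with Beer–Lambert attenuation
and optional seeded Poisson noise. Counts are integers; negative
bin-subtraction results under noise are clipped to zero and counted.

## The temperature regressor

The network input concatenates a material's four per-bin LACs at the
current temperature with the four heating residuals above the baseline
scan, the residuals scaled by exactly 100 to bring them into the numeric
range of the LACs (`build_feature()`):

$$x = \big[\mu(T,E_1..E_4),\ (\mu(T,E_k)-\mu(T_0,E_k))\cdot 100\big].$$

The architecture is fully connected 8–4–4–1 with ReLU activation, mean
squared error loss, and per-sample stochastic gradient descent at
learning rate $10^{-5}$; the data are split 80/20 into training and
validation, stratified by material (`regressor_spec()`,
`train_regressor()`). Training data are generated from the base series:
333 temperatures per material on a uniform grid over 33–90 °C, each
interpolated LAC perturbed with zero-mean Gaussian noise
(`generate_training_set()`).

Choices the printed protocol leaves open, and what this package does:

- **Training noise.** The magnitude and character of the input noise are
  configurable; the default is relative, SD = 0.5% of each bin's
  baseline LAC (`noise_sd_rel = 0.005`), comparable to the 10-LOI spread
  of simulated acquisitions at the default flux.
- **Initialisation.** Fan-in-scaled Gaussian weights
  (SD $= \sqrt{2/n_{in}}$) with small positive biases, seeded; a
  zero-initialised ReLU stack is completely dead (every gradient is
  zero), which the test suite uses as a frozen-optimizer check.
- **Output activation.** ReLU on the output as well as the hidden
  layers; with targets in °C (always positive) the output rectifier is
  non-binding after the first epochs, and it can be disabled
  (`output_relu = FALSE`).
- **Epochs.** With a $10^{-5}$ learning rate and features of magnitude
  $10^{-2}$–$1$, the optimisation needs on the order of $10^3$ epochs on
  the default synthetic data: the mean response is captured in the first
  ~100 epochs and the material-dependent shaping continues well past
  500. The default is `max_epochs = 1000`; optional early stopping by
  validation patience is available but off by default, so runs are
  deterministic in length.
- **Returned weights.** Per-sample SGD never settles: near the optimum
  the iterate keeps oscillating (validation MAE can change by ~15%
  between adjacent epochs). The returned weights are therefore the
  Polyak–Ruppert average of the iterates over the final 20% of epochs
  (`average_tail = 0.2`), a classical lower-variance estimate of the
  underlying optimum. Single-epoch alternatives were considered and
  rejected: the final iterate inherits the oscillation, and picking the
  best-validation checkpoint selects weights specialised to the three
  training materials at the expense of interpolating between them. The
  per-epoch history always records the raw iterates.

Prediction uncertainty (`predict_with_ci()`) follows the measurement
model: the four LAC components of the feature are perturbed with
Gaussian noise of the supplied per-bin variance (as estimated across 10
adjacent LOIs), the residual half is re-derived from each perturbed LAC,
and the 2.5–97.5 percentile range of the predictions over (by default)
1000 draws forms the interval around the noiseless prediction.

## The synthetic data generator

The generator (`material_spec()`, `sensitivity_law()`,
`make_base_series()`, `make_test_materials()`, `make_phantom_scene()`)
emulates the statistical structure of the measured thermal series, not
their physics:

- Per-bin LAC is linear in temperature with the measured sign pattern:
  positive slope in the 33–45 keV bin (reduced Compton scattering of
  higher-energy photons), negative in the other three. Series are
  sampled every 5 °C by default.
- Baseline LACs are water-like in magnitude
  ((0.052, 0.027, 0.0225, 0.0185) mm$^{-1}$); CaCl$_2$ adds a per-bin
  linear concentration increment plus a small quadratic non-ideality so
  that the three bases (water, 50 and 600 mmol/L) span a genuinely
  three-dimensional spectral subspace. Slope magnitudes
  ($10^{-5}$–$10^{-4}$ mm$^{-1}$/°C) place the ×100-scaled residuals in
  the baseline LAC's numeric range, as the feature design intends.
- Thermal sensitivity follows a quadratic law in concentration
  (default factor $1 + u + 0.8u^2$, $u = c/600$), so the 300 mmol/L
  slope is *not* the midpoint of the 0 and 600 mmol/L slopes — the
  non-linearity the regressor must capture and the linear mixture model
  provably misses.
- The *similar* test material (300 mmol/L-like, evaluated over
  35–60 °C) has the exact 50/50 water + 600 mmol/L baseline but the
  law's non-linear slope. The *dissimilar* surrogate (38–50 °C) has a
  baseline perturbed off the base span by up to 5% per bin and
  independently perturbed slopes (±10%) with the standard sign pattern;
  it is a perturbed-attenuation construct, not a model of any organic
  liquid's composition.

What the generator does **not** emulate: physical energy spectra and
detector response (charge sharing, fluorescence escape, pixel gaps —
only an optional dead-column mask), beam hardening, scatter (only its
phenomenological sign effect on the 33–45 keV slope), or absolute
agreement of LAC magnitudes with tabulated reference data. Passing
tests therefore demonstrate that the *pipeline* — simulation,
extraction, decomposition, training, prediction — is internally
consistent and recovers known synthetic parameters; they do not certify
accuracy on real measurements.

## Numerical choices and degenerate inputs

- LAC units are mm$^{-1}$ everywhere internally; the integration
  constants (pitch, $L$) are in mm.
- Profile integration is trapezoidal over all columns with masked
  columns linearly interpolated; a profile that does not decay to ~0 at
  its ends triggers an incomplete-shadow warning (the estimate is biased
  low). At very low dose this heuristic can fire on pure edge noise.
- Counts are stored as 16-bit TIFF; the default per-bin flux (12 000)
  keeps the open-threshold sum of four bins inside the 16-bit range.
- Zero/negative counts on a valid column are masked (log undefined),
  never fatal; an all-masked profile is a degenerate-profile error.
- Decomposition refuses bases with condition number above $10^{10}$
  (collinear bases) and reports the condition number.
- Interpolation of thermal series is linear per bin; temperatures
  outside a series' range are extrapolation errors, never extrapolated.
- All stochastic stages (Poisson counts, training noise, splits,
  shuffling, Monte-Carlo draws) take explicit integer seeds and are
  bitwise reproducible.

## Interval calibration: a known limitation

The Monte-Carlo interval propagates *measurement noise only*, following
the design of the uncertainty procedure it implements. The regressor
itself carries a residual systematic error of roughly 0.5–1 °C on clean
inputs. The package's calibration study (in the acceptance suite:
200 cases, base materials, noise on the observed LACs exactly equal to
the variance handed to `predict_with_ci()`, at the default 0.5%
measurement noise) measures empirical coverage of the true temperature
a few points *below* the nominal 95% band — about 87% in our runs —
because the interval does not model that bias. Coverage approaches
nominal only when measurement noise dominates the regressor's bias
(low-dose regimes); conversely, judging a 10-LOI *mean* measurement
against the per-LOI variance (the conservative reading of the printed
procedure) over-covers at essentially 100%. Users who need calibrated
intervals at high dose should add a model-error term; the package keeps
the noise-only procedure as specified.

## Problem sizes used by the test suite

The simulation tests use the self-consistent geometry at 16–232 detector
rows and 640–1280 columns (the LOI chain only needs the rows it
averages), per-bin fluxes of 1 500–500 000 counts/pixel, and the default
training configuration of 999 rows × 1000 epochs; the end-to-end
acceptance checks train three seeds and evaluate both synthetic test
materials. These sizes are the package's chosen defaults for its own
validation study.

## Known limitations

- The LOI method is strictly one-dimensional; no tomographic
  reconstruction or 2D attenuation mapping is provided.
- The linear-in-temperature synthetic trend means the generator cannot
  probe curvature in $\mu(T)$ within a single material.
- The dissimilar-material surrogate is an attenuation-space
  perturbation; conclusions about truly organic materials require
  measured data.
- Interval under-coverage in bias-dominated regimes, as described
  above.
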