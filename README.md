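# pcctherm

X-ray CT thermometry with photon-counting detectors, in R.

Thermal ablation (focused ultrasound, radiofrequency) needs volumetric,
real-time temperature maps. CT can provide them because heating expands a
material and lowers its linear attenuation coefficient (LAC, μ), but the
attenuation-per-degree *thermal sensitivity* differs between tissues, so
classical single-energy CT thermometry requires per-material calibration.
A photon-counting detector measures attenuation in several energy bins at
once (here 8–33, 33–45, 45–60 and 60–100 keV), which enables material
decomposition and, from it, calibration-free temperature prediction.

`pcctherm` implements that pipeline end to end, for researchers in
spectral CT and image-guided thermal therapy:

- **Projection simulation** — fan-beam Beer–Lambert projections of a
  square liquid phantom (empty and filled), threshold acquisitions and
  their subtraction into energy bins, seeded Poisson noise, 16-bit TIFF
  I/O with JSON sidecars.
- **LAC extraction** — the line-of-interest (LOI) profile method:
  3-SD unstable-pixel masking, the log-ratio profile difference
  Δp(x) = ln(I_e/I_f) (enclosure attenuation cancels), a 5-pixel mean
  then 7-pixel median filter, and the weak-perspective integral
  μ = (p/L²) Σ Δp(x)/M with M ≈ 1.23 the geometric magnification;
  mean and variance over 10 adjacent LOIs.
- **Material model** — spectral mixing μ(E_k) = Σ V_i μ_i(E_k),
  sum-constrained least-squares decomposition over all four bins,
  Hounsfield conversion, the ΔCT ≈ −(1000 + CT(T₀)) α ΔT expansion
  model, per-bin sensitivity fits, and the (deliberately inadequate)
  linear mixture thermal model α′ = Σ V_i α_i.
- **Temperature regressor** — an 8–4–4–1 ReLU network on features
  [μ(T,·), (μ(T,·) − μ(T₀,·))·100], trained by per-sample SGD
  (lr 1e-5, MSE, 80/20 stratified split, 333 inputs per base material),
  with Monte-Carlo 95% prediction intervals driven by the measured
  10-LOI attenuation variance.
- **Synthetic data** — thermal series with the measured sign pattern
  (positive slope only in 33–45 keV) and a quadratic
  sensitivity-vs-concentration law, plus similar (300 mmol/L-like) and
  dissimilar (organic-surrogate) test materials, so the whole pipeline
  is testable without any external dataset.

## Worked example

```r
library(pcctherm)

## base materials: water, 50 and 600 mmol/L CaCl2 (synthetic series)
bases <- default_base_set()

## spectral decomposition of an equal-volume water + 600 mmol/L mixture
decompose_lac(mix_spectral_lac(c(0.5, 0, 0.5), bases), bases)
#> Volume fractions (sum constrained to 1):
#>         water  cacl2_50mmol cacl2_600mmol
#>           0.5           0.0           0.5
#>   residual norm: 3.09e-15

## simulate an acquisition and re-extract the spectral LAC
g <- consistent_geometry(detector_rows = 16)
scene <- make_phantom_scene(g, bases$bases$water, temperature_C = 53,
                            noise = TRUE, seed = 7)
frames <- scene_bin_frames(scene)
lac_with_variance(frames$filled, frames$empty, g, center_row = 4, n_loi = 10)
#> LAC measurement (mm^-1), mean over 10 LOIs
#>   bin         mu          var n_effective
#> 1   1 0.05088217 1.022160e-08          10
#> 2   2 0.02755923 2.784774e-09          10
#> 3   3 0.02169900 3.026529e-09          10
#> 4   4 0.01793177 1.074811e-09          10

## train the regressor and evaluate the two held-out test materials
ts <- generate_training_set(bases, n_per_material = 333, seed = 1)
model <- train_regressor(ts, regressor_spec(seed = 1))
model
#> Temperature regressor 8-4-4-1, 1000 epochs
#>   validation MAE: 57.56 degC (epoch 1) -> 1.47 degC (final)
```

The decomposition recovers the known volume fractions to numerical
precision (the mixture is in the span of the bases, hence the ~1e-15
residual); the extracted LACs agree with the generating values to within
the ~3% weak-perspective bound (here ≤ 0.3%); training converges from a
~58 °C initial validation error to ~1.5 °C. On the held-out synthetic
test materials the trained model reaches

```r
#> MAE similar (300 mmol/L-like, 35-60 degC): 1.97 degC
#> MAE dissimilar (organic surrogate, 38-50 degC): 1.13 degC
```

and a single prediction with a measurement-noise confidence interval:

```r
p <- predict_with_ci(model, feature, var_per_bin, seed = 1)
#> T = 53.94 degC  (95% CI 50.04 - 57.82, 1000 draws)   # true T was 55.0
```

See `vignettes/pcct-thermometry.Rmd` for the models, every tunable
parameter, and the design decisions (including why intervals can
under-cover when measurement noise is small).

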