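bases <- default_base_set()

test_that("mixing is the fraction-weighted spectral sum", {
  w <- series_lac_at(bases$bases$water, 33)
  expect_equal(mix_spectral_lac(c(1, 0, 0), bases)$mu_per_bin, w$mu_per_bin)

  mid <- mix_spectral_lac(c(0.5, 0, 0.5), bases)
  m600 <- series_lac_at(bases$bases$cacl2_600mmol, 33)
  expect_equal(mid$mu_per_bin, (w$mu_per_bin + m600$mu_per_bin) / 2)

  set.seed(5)
  for (i in 1:20) {
    f <- as.numeric(rmultinom(1, 1000, c(1, 1, 1))) / 1000
    mus <- vapply(bases$bases, function(b) series_lac_at(b, 40)$mu_per_bin,
                  numeric(4))
    expect_equal(mix_spectral_lac(f, bases, 40)$mu_per_bin,
                 drop(mus %*% f), tolerance = 1e-12)
  }
  expect_error(mix_spectral_lac(c(0.5, 0.5, 0.5), bases), "sum to 1")
  expect_error(mix_spectral_lac(c(1, 0, 0), bases, temperature_C = 20),
               "extrapolation")
})

test_that("constrained decomposition inverts mixing on the simplex", {
  d <- decompose_lac(mix_spectral_lac(c(1, 0, 0), bases), bases)
  expect_equal(unname(d$fractions), c(1, 0, 0), tolerance = 1e-10)
  expect_lt(d$residual_norm, 1e-12)

  d50 <- decompose_lac(mix_spectral_lac(c(0.5, 0, 0.5), bases), bases)
  expect_equal(unname(d50$fractions), c(0.5, 0, 0.5), tolerance = 1e-10)
  expect_equal(sum(d50$fractions), 1, tolerance = 1e-12)

  set.seed(9)
  worst <- 0
  for (i in 1:200) {
    f <- as.numeric(rmultinom(1, 10000, runif(3, 0.2, 1))) / 10000
    d <- decompose_lac(mix_spectral_lac(f, bases), bases)
    worst <- max(worst, max(abs(unname(d$fractions) - f)))
    expect_equal(sum(d$fractions), 1, tolerance = 1e-12)
  }
  expect_lt(worst, 1e-8)
})

test_that("collinear bases raise an ill-conditioning error", {
  # three solutions whose baselines are exactly linear in concentration
  # span only a 2-D spectral subspace
  lin_mu0 <- function(c) c(0.052, 0.027, 0.0225, 0.0185) +
    c(3e-5, 1.2e-5, 6e-6, 3e-6) * c
  mk <- function(c, name) {
    temps <- seq(33, 93, by = 10)
    thermal_series(name, temps,
                   outer(rep(1, length(temps)), lin_mu0(c)))
  }
  degenerate <- base_material_set(list(mk(0, "a"), mk(50, "b"), mk(600, "c")))
  tgt <- spectral_lac("t", 33, lin_mu0(300))
  expect_error(decompose_lac(tgt, degenerate), "ill-conditioned")
})

test_that("Hounsfield conversion anchors water at 0 and vacuum at -1000", {
  expect_equal(lac_to_hu(0.02, 0.02), 0)
  expect_equal(lac_to_hu(0, 0.02), -1000)
  expect_equal(lac_to_hu(0.04, 0.02), 1000)
  expect_error(lac_to_hu(0.02, 0), "mu_water")
  mu <- seq(0.01, 0.05, by = 0.005)
  expect_true(all(diff(lac_to_hu(mu, 0.022)) > 0))
})

test_that("thermal CT-number change follows the expansion model", {
  expect_equal(predict_delta_ct(120, 4e-4, 0), 0)
  expect_equal(predict_delta_ct(0, 4e-4, 10), -4.0)
  expect_equal(predict_delta_ct(-1000, 0.01, 55), 0)
  # heating a water-like material lowers its CT number
  expect_lt(predict_delta_ct(0, 4e-4, 30), 0)
})

test_that("sensitivity fitting recovers linear series and flags short ones", {
  sp <- cacl2_material(50)
  s <- make_base_series(sp, seq(33, 88, by = 5), noise_sd_rel = 0)
  fit <- fit_thermal_sensitivity(s)
  expect_equal(fit$slope_per_bin, sp$slope_per_bin, tolerance = 1e-10)
  expect_equal(fit$intercept_per_bin, sp$mu0_per_bin, tolerance = 1e-10)
  expect_equal(fit$r2_per_bin, rep(1, 4), tolerance = 1e-9)

  const <- thermal_series("c", c(33, 50, 70),
                          matrix(0.03, 3, 4))
  fc <- fit_thermal_sensitivity(const)
  expect_equal(fc$slope_per_bin, rep(0, 4), tolerance = 1e-15)

  short <- thermal_series("s", c(33, 50), matrix(0.03, 2, 4))
  expect_error(fit_thermal_sensitivity(short), "insufficient")
})

test_that("noisy sensitivity estimates are unbiased", {
  sp <- cacl2_material(50)
  slopes <- t(vapply(1:50, function(sd)
    fit_thermal_sensitivity(make_base_series(sp, seq(33, 88, by = 5),
                                             noise_sd_rel = 0.01,
                                             seed = sd))$slope_per_bin,
    numeric(4)))
  for (b in 1:4) {
    se <- sd(slopes[, b]) / sqrt(50)
    expect_lt(abs(mean(slopes[, b]) - sp$slope_per_bin[b]), 2.5 * se + 1e-12)
  }
})

test_that("the linear mixture model weights slopes and offsets by fraction", {
  fits <- lapply(bases$bases, fit_thermal_sensitivity)
  one <- linear_mixture_thermal_model(c(1, 0, 0), fits)
  expect_equal(one$alpha_prime, fits[[1]]$slope_per_bin)
  expect_equal(one$beta_prime, fits[[1]]$intercept_per_bin)

  two_same <- linear_mixture_thermal_model(c(0.5, 0.5), fits[c(1, 1)])
  expect_equal(two_same$alpha_prime, fits[[1]]$slope_per_bin)

  f <- c(0.2, 0.3, 0.5)
  mixed <- linear_mixture_thermal_model(f, fits)
  brute <- rep(0, 4)
  for (i in 1:3) brute <- brute + f[i] * fits[[i]]$slope_per_bin
  expect_equal(mixed$alpha_prime, brute, tolerance = 1e-14)
})

test_that("the linear mixture model misses materials with non-linear sensitivity", {
  # the 300 mmol/L-like material is a true volumetric mixture by baseline,
  # but its slope follows the quadratic law, not the fraction-weighted one
  tests <- make_test_materials()
  similar <- tests$similar
  fr <- decompose_lac(series_lac_at(similar, 33), bases)
  expect_equal(unname(fr$fractions), c(0.5, 0, 0.5), tolerance = 1e-6)
  fits <- lapply(bases$bases, fit_thermal_sensitivity)
  lin <- linear_mixture_thermal_model(fr, fits)
  true_slope <- fit_thermal_sensitivity(similar)$slope_per_bin
  # systematic slope error of the linear baseline, well above fit noise
  expect_gt(max(abs(lin$alpha_prime - true_slope) / abs(true_slope)), 0.05)
})
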