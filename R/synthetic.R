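#' Synthetic material specification
#'
#' Baseline spectral LAC at 33 degC plus a per-bin linear thermal slope.
#' The default sign pattern matches what photon-counting measurements of
#' aqueous solutions show: attenuation falls with temperature in every bin
#' except 33-45 keV, where reduced Compton scattering of higher-energy
#' photons makes it rise.
#'
#' @param name Material label.
#' @param mu0_per_bin Baseline LAC at 33 degC per bin (mm^-1, positive).
#' @param slope_per_bin LAC change per degC per bin (mm^-1/degC).
#' @param concentration_mmol CaCl2 concentration (mmol/L), `NA` for
#'   organic surrogates.
#' @param enforce_sign_pattern Require slope > 0 in bin 2 and < 0
#'   elsewhere.
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(name, mu0_per_bin, slope_per_bin,
                          concentration_mmol = NA_real_,
                          enforce_sign_pattern = TRUE) {
  mu0_per_bin <- as.numeric(mu0_per_bin)
  slope_per_bin <- as.numeric(slope_per_bin)
  if (any(mu0_per_bin <= 0)) stop("mu0_per_bin must be strictly positive")
  if (enforce_sign_pattern &&
      !(slope_per_bin[2] > 0 && all(slope_per_bin[-2] < 0)))
    stop("slope sign pattern violated: expect > 0 in bin 2 (33-45 keV), < 0 elsewhere")
  if (any(abs(slope_per_bin) * 60 >= mu0_per_bin))
    stop("spec invalid: slopes would drive the LAC non-positive within 60 degC")
  structure(list(name = name, mu0_per_bin = mu0_per_bin,
                 slope_per_bin = slope_per_bin,
                 concentration_mmol = concentration_mmol),
            class = "material_spec")
}

#' Quadratic sensitivity-vs-concentration law
#'
#' Thermal sensitivity is driven by thermal expansion and hence by
#' intermolecular bonding, so it is not linear in solute concentration:
#' measured CaCl2 series show a quadratic-or-higher trend. The law maps a
#' concentration (mmol/L) to per-bin slopes through per-bin quadratic
#' coefficients; the default is
#' `slope(c) = a * (1 + u + 0.8 u^2)` with `u = c / 600` and `a` the water
#' slopes, so sensitivity grows faster than linearly and the 300 mmol/L
#' slope is not the midpoint of the 0 and 600 mmol/L slopes.
#'
#' @param c0,c1,c2 Per-bin coefficient 4-vectors of the quadratic
#'   `slope(c) = c0 + c1 c + c2 c^2`.
#' @return An object of class `sensitivity_law`.
#' @export
sensitivity_law <- function(c0 = c(-6e-5, 2.5e-5, -4e-5, -3e-5),
                            c1 = c0 / 600,
                            c2 = 0.8 * c0 / 600^2) {
  if (all(c2 == 0)) stop("law must be strictly non-linear (quadratic term != 0)")
  structure(list(c0 = as.numeric(c0), c1 = as.numeric(c1), c2 = as.numeric(c2)),
            class = "sensitivity_law")
}

#' Per-bin thermal slope at a CaCl2 concentration
#'
#' @param c_mmol Concentration (mmol/L, >= 0).
#' @param law A [sensitivity_law()].
#' @return 4-vector of slopes (mm^-1/degC).
#' @export
sensitivity_from_concentration <- function(c_mmol, law = sensitivity_law()) {
  stopifnot(inherits(law, "sensitivity_law"), c_mmol >= 0)
  law$c0 + law$c1 * c_mmol + law$c2 * c_mmol^2
}

# baseline LAC of a CaCl2 solution: water plus a per-bin concentration
# increment (photoelectric contribution of the salt) with a small per-bin
# quadratic non-ideality, so the three bases span a genuinely 3-D
# spectral subspace
default_water_mu0 <- function() c(0.052, 0.027, 0.0225, 0.0185)
default_conc_coeff <- function() c(3e-5, 1.2e-5, 6e-6, 3e-6)
default_conc_quad <- function() c(-1.2e-8, 6e-9, 4e-9, 1.5e-9)

#' Baseline spectral LAC of a CaCl2 solution under the synthetic model
#'
#' `mu0(c) = mu0_water + k c + q c^2` per bin at 33 degC, with `k` the
#' linear salt contribution and `q` a small non-ideality term.
#'
#' @param c_mmol Concentration (mmol/L).
#' @return 4-vector of baseline LACs (mm^-1).
#' @export
cacl2_baseline_mu0 <- function(c_mmol) {
  default_water_mu0() + default_conc_coeff() * c_mmol +
    default_conc_quad() * c_mmol^2
}

#' Material spec for a CaCl2 solution under the default synthetic model
#'
#' Baseline LAC is water's plus a per-bin linear concentration increment;
#' the thermal slope follows the (non-linear) sensitivity law.
#'
#' @param c_mmol Concentration (mmol/L).
#' @param law A [sensitivity_law()].
#' @param name Optional label.
#' @return A [material_spec()].
#' @export
cacl2_material <- function(c_mmol, law = sensitivity_law(),
                           name = if (c_mmol == 0) "water"
                                  else sprintf("cacl2_%gmmol", c_mmol)) {
  material_spec(name,
                mu0_per_bin = cacl2_baseline_mu0(c_mmol),
                slope_per_bin = sensitivity_from_concentration(c_mmol, law),
                concentration_mmol = c_mmol)
}

#' Generate a thermal series from a material spec
#'
#' `mu(T, bin) = mu0 + slope * (T - 33)` plus seeded Gaussian noise of SD
#' `noise_sd_rel * mu0` per bin, at the given temperatures (default every
#' 5 degC from 33 to 88, emulating readings taken at roughly every 5 degC
#' of transient cooling).
#'
#' @param spec A [material_spec()].
#' @param temperatures_C Temperatures (degC) within [30, 95]; must include
#'   the 33 degC baseline.
#' @param noise_sd_rel Relative noise SD (0 for the exact trend).
#' @param seed Integer seed.
#' @return A [thermal_series()].
#' @export
make_base_series <- function(spec, temperatures_C = seq(33, 88, by = 5),
                             noise_sd_rel = 0, seed = 1L) {
  stopifnot(inherits(spec, "material_spec"))
  if (any(temperatures_C < 30 | temperatures_C > 95))
    stop("temperatures must lie within [30, 95] degC")
  if (!any(abs(temperatures_C - 33) < 1e-9))
    stop("temperatures must include the 33 degC baseline")
  set.seed(as.integer(seed))
  nb <- length(spec$mu0_per_bin)
  mu <- outer(temperatures_C - 33, spec$slope_per_bin) +
    matrix(spec$mu0_per_bin, length(temperatures_C), nb, byrow = TRUE)
  if (noise_sd_rel > 0)
    mu <- mu + matrix(stats::rnorm(length(mu),
                                   sd = rep(noise_sd_rel * spec$mu0_per_bin,
                                            each = length(temperatures_C))),
                      length(temperatures_C), nb)
  if (any(mu <= 0)) stop("spec invalid: generated LAC non-positive")
  thermal_series(spec$name, temperatures_C, mu, baseline_C = 33)
}

#' Default synthetic base-material set
#'
#' Water, 50 mmol/L CaCl2 and 600 mmol/L CaCl2 series over 33-90 degC.
#'
#' @param law A [sensitivity_law()].
#' @param noise_sd_rel Relative noise SD on the series.
#' @param seed Integer seed.
#' @return A [base_material_set()].
#' @export
default_base_set <- function(law = sensitivity_law(), noise_sd_rel = 0,
                             seed = 1L) {
  temps <- seq(33, 93, by = 5)
  base_material_set(lapply(seq_along(cc <- c(0, 50, 600)), function(i)
    make_base_series(cacl2_material(cc[i], law), temps,
                     noise_sd_rel = noise_sd_rel, seed = seed + i)))
}

#' Synthetic test materials: similar and dissimilar
#'
#' The similar material emulates 300 mmol/L CaCl2 over 35-60 degC: its
#' baseline LAC equals the 50/50 water + 600 mmol/L mixture exactly, but
#' its thermal slope follows the non-linear law at 300 mmol/L — so a
#' linear volumetric mixture model misses it by construction. The
#' dissimilar material emulates an organic liquid over 38-50 degC: its
#' baseline is a seeded perturbation (up to 5 percent per bin) off the
#' base-material span and its slopes are independently perturbed while
#' keeping the standard sign pattern.
#'
#' @param law A [sensitivity_law()].
#' @param seed Integer seed for the dissimilar perturbations.
#' @return List with `similar` and `dissimilar` [thermal_series()].
#' @export
make_test_materials <- function(law = sensitivity_law(), seed = 1L) {
  mu0_similar <- (cacl2_baseline_mu0(0) + cacl2_baseline_mu0(600)) / 2
  similar <- material_spec("cacl2_300mmol_test", mu0_similar,
                           sensitivity_from_concentration(300, law),
                           concentration_mmol = 300)
  set.seed(as.integer(seed))
  mu0_dis <- cacl2_baseline_mu0(150) * (1 + stats::runif(4, -0.05, 0.05))
  slope_dis <- sensitivity_from_concentration(150, law) *
    stats::runif(4, 0.9, 1.1)
  dissimilar <- material_spec("organic_surrogate", mu0_dis, slope_dis)
  list(
    similar = make_base_series(similar, c(33, seq(35, 60, by = 2.5)),
                               noise_sd_rel = 0, seed = seed),
    dissimilar = make_base_series(dissimilar, c(33, seq(38, 50, by = 2)),
                                  noise_sd_rel = 0, seed = seed))
}

#' Simulate a full phantom acquisition for one material and temperature
#'
#' Interpolates the material's per-bin LAC at the requested temperature and
#' composes the projection simulator into the two paired threshold
#' acquisitions a photon-counting detector would record (8/45 keV then
#' 33/60 keV thresholds, empty and filled), consistent with
#' [counts_to_bins()] inversion. The two acquisitions carry independent
#' counting noise.
#'
#' @param geometry A [phantom_geometry()].
#' @param series A [thermal_series()].
#' @param temperature_C Temperature within the series range.
#' @param flux_per_bin Incident counts per pixel per bin. The default of
#'   12000 keeps the open-threshold sum of four bins within the 16-bit
#'   range used for frame storage.
#' @param noise Logical; Poisson counting noise.
#' @param seed Integer seed.
#' @return List with `thresholds` (list `empty`, `filled`, each holding
#'   frames named t8, t33, t45, t60), `mu_per_bin` (the interpolated
#'   truth), and `geometry`.
#' @export
make_phantom_scene <- function(geometry, series, temperature_C,
                               flux_per_bin = 12000, noise = FALSE,
                               seed = 1L) {
  stopifnot(inherits(series, "thermal_series"))
  mu <- series_lac_at(series, temperature_C)$mu_per_bin
  acqA <- simulate_projection_pair(geometry, mu, flux_per_bin, noise = noise,
                                   seed = seed, binning = series$binning)
  acqB <- simulate_projection_pair(geometry, mu, flux_per_bin, noise = noise,
                                   seed = seed + 1L, binning = series$binning)
  sum_bins <- function(frames, keep) Reduce(`+`, lapply(frames[keep], `[[`, "counts"))
  thr <- function(acq, side) list(
    t8 = sum_bins(acq[[side]], 1:4),
    t45 = sum_bins(acq[[side]], 3:4),
    t33 = sum_bins(acq[[side]], 2:4),
    t60 = sum_bins(acq[[side]], 4))
  empty <- c(thr(acqA, "empty")[c("t8", "t45")], thr(acqB, "empty")[c("t33", "t60")])
  filled <- c(thr(acqA, "filled")[c("t8", "t45")], thr(acqB, "filled")[c("t33", "t60")])
  list(thresholds = list(empty = empty, filled = filled),
       mu_per_bin = mu, temperature_C = temperature_C,
       material = series$material, geometry = geometry, seed = as.integer(seed))
}

#' Per-bin frames from a phantom scene
#'
#' Applies threshold subtraction to both the empty and filled acquisitions
#' of a scene.
#'
#' @param scene A [make_phantom_scene()] result.
#' @return List with `empty` and `filled`, each a list of 4 per-bin count
#'   matrices.
#' @export
scene_bin_frames <- function(scene) {
  th <- scene$thresholds
  list(
    empty = counts_to_bins(list(th$empty$t8, th$empty$t45),
                           list(th$empty$t33, th$empty$t60))$bins,
    filled = counts_to_bins(list(th$filled$t8, th$filled$t45),
                            list(th$filled$t33, th$filled$t60))$bins)
}
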