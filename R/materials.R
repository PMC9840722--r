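#' Thermal series of spectral LACs for one material
#'
#' A table of per-bin linear attenuation coefficients measured (or
#' generated) at a set of temperatures, with a baseline temperature
#' (default 33 degC) against which heating residuals are computed.
#'
#' @param material Material label.
#' @param temperatures_C Numeric vector of temperatures (degC).
#' @param mu Matrix `length(temperatures_C) x n_bins` of LACs (mm^-1).
#' @param baseline_C Baseline temperature (degC).
#' @param binning An [energy_binning()].
#' @return An object of class `thermal_series`.
#' @export
thermal_series <- function(material, temperatures_C, mu, baseline_C = 33,
                           binning = energy_binning()) {
  mu <- as.matrix(mu)
  if (nrow(mu) != length(temperatures_C))
    stop("mu must have one row per temperature")
  if (ncol(mu) != binning$n_bins)
    stop("mu must have one column per energy bin")
  if (any(mu <= 0)) stop("LACs must be strictly positive")
  o <- order(temperatures_C)
  structure(list(material = material,
                 temperatures_C = as.numeric(temperatures_C)[o],
                 mu = mu[o, , drop = FALSE],
                 baseline_C = baseline_C,
                 binning = binning),
            class = "thermal_series")
}

#' @export
print.thermal_series <- function(x, ...) {
  cat(sprintf("Thermal series '%s': %d temperatures (%g-%g degC), baseline %g degC\n",
              x$material, length(x$temperatures_C), min(x$temperatures_C),
              max(x$temperatures_C), x$baseline_C))
  invisible(x)
}

#' Interpolate a thermal series at a temperature
#'
#' Linear interpolation per energy bin. Temperatures outside the measured
#' range raise an extrapolation error.
#'
#' @param series A [thermal_series()].
#' @param temperature_C Temperature (degC).
#' @return A `spectral_lac`: list with `material_id`, `temperature_C`,
#'   `mu_per_bin`.
#' @export
series_lac_at <- function(series, temperature_C) {
  stopifnot(inherits(series, "thermal_series"))
  tr <- range(series$temperatures_C)
  if (temperature_C < tr[1] - 1e-9 || temperature_C > tr[2] + 1e-9)
    stop(sprintf("extrapolation: %g degC outside series range [%g, %g]",
                 temperature_C, tr[1], tr[2]))
  mu <- vapply(seq_len(ncol(series$mu)), function(b)
    stats::approx(series$temperatures_C, series$mu[, b],
                  xout = temperature_C, rule = 2)$y, numeric(1))
  spectral_lac(series$material, temperature_C, mu)
}

#' Spectral LAC of a material at one temperature
#' @param material_id Material label.
#' @param temperature_C Temperature (degC); must lie in 20-95.
#' @param mu_per_bin Positive 4-vector of LACs (mm^-1).
#' @return An object of class `spectral_lac`.
#' @export
spectral_lac <- function(material_id, temperature_C, mu_per_bin) {
  mu_per_bin <- as.numeric(mu_per_bin)
  if (any(mu_per_bin <= 0)) stop("mu_per_bin must be strictly positive")
  if (temperature_C < 20 || temperature_C > 95)
    stop("temperature outside the supported 20-95 degC range")
  structure(list(material_id = material_id, temperature_C = temperature_C,
                 mu_per_bin = mu_per_bin),
            class = "spectral_lac")
}

#' Base material set
#'
#' The ordered set of base materials whose spectral LAC series span the
#' decomposition. The canonical choice is water, 50 mmol/L CaCl2 and
#' 600 mmol/L CaCl2: the body is characteristically water and bone-like
#' mineral, and the two salt concentrations bracket mineral content.
#'
#' @param bases List of [thermal_series()], all sharing binning and
#'   baseline temperature.
#' @return An object of class `base_material_set`.
#' @export
base_material_set <- function(bases) {
  if (length(bases) < 2L) stop("need at least 2 base materials")
  if (!all(vapply(bases, inherits, logical(1), "thermal_series")))
    stop("bases must be thermal_series objects")
  b0 <- bases[[1]]
  same <- vapply(bases, function(b)
    identical(b$binning$edges_kev, b0$binning$edges_kev) &&
      isTRUE(all.equal(b$baseline_C, b0$baseline_C)), logical(1))
  if (!all(same)) stop("all bases must share energy binning and baseline temperature")
  names(bases) <- vapply(bases, `[[`, character(1), "material")
  structure(list(bases = bases, baseline_C = b0$baseline_C,
                 binning = b0$binning),
            class = "base_material_set")
}

#' Mix base materials into a spectral LAC
#'
#' The LAC of a volumetric mixture is the volume-fraction-weighted sum of
#' the base LACs, per energy bin, at the given temperature.
#'
#' @param fractions Numeric vector of volume fractions aligned to the
#'   bases; must sum to 1.
#' @param bases A [base_material_set()].
#' @param temperature_C Temperature at which base LACs are interpolated.
#' @return A [spectral_lac()] for the mixture.
#' @export
mix_spectral_lac <- function(fractions, bases, temperature_C = bases$baseline_C) {
  stopifnot(inherits(bases, "base_material_set"))
  fractions <- as.numeric(fractions)
  if (length(fractions) != length(bases$bases))
    stop("fractions must align with the bases")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1")
  mus <- vapply(bases$bases, function(b)
    series_lac_at(b, temperature_C)$mu_per_bin,
    numeric(bases$binning$n_bins))
  mu <- drop(mus %*% fractions)
  spectral_lac(paste0("mix(", paste(signif(fractions, 6), collapse = ","), ")"),
               temperature_C, mu)
}

#' Decompose a spectral LAC into base-material volume fractions
#'
#' Solves the spectral mixture system as an equality-constrained
#' least-squares problem: the four per-bin mixture equations are fit in
#' least squares while the volume fractions are constrained to sum to one
#' exactly (KKT system). Fractions outside [0, 1] are reported raw with a
#' flag, never clipped, so the residual remains diagnostic for materials
#' outside the span of the bases.
#'
#' @param target A [spectral_lac()] to decompose.
#' @param bases A [base_material_set()].
#' @param temperature_C Temperature at which base LACs are taken (default:
#'   the common baseline).
#' @return An object of class `volume_fractions`: list with `fractions`,
#'   `residual_norm` (Euclidean norm of the spectral residual),
#'   `outside_unit_interval` flag, and `condition_number` of the basis
#'   matrix.
#' @export
decompose_lac <- function(target, bases, temperature_C = bases$baseline_C) {
  stopifnot(inherits(target, "spectral_lac"), inherits(bases, "base_material_set"))
  A <- vapply(bases$bases, function(b)
    series_lac_at(b, temperature_C)$mu_per_bin,
    numeric(bases$binning$n_bins))   # n_bins x n_bases
  y <- target$mu_per_bin
  m <- ncol(A)
  if (nrow(A) < m - 1L) stop("need at least n_bases - 1 energy bins")
  kap <- kappa(A, exact = TRUE)
  if (kap > 1e10)
    stop(sprintf("ill-conditioned basis: condition number %.3g (collinear bases)", kap))
  # minimise ||A v - y||^2 subject to sum(v) = 1
  K <- rbind(cbind(2 * crossprod(A), rep(1, m)),
             c(rep(1, m), 0))
  rhs <- c(2 * crossprod(A, y), 1)
  sol <- solve(K, rhs)
  v <- sol[seq_len(m)]
  res <- sqrt(sum((A %*% v - y)^2))
  structure(list(fractions = stats::setNames(v, names(bases$bases)),
                 residual_norm = res,
                 outside_unit_interval = any(v < 0 | v > 1),
                 condition_number = kap),
            class = "volume_fractions")
}

#' @export
print.volume_fractions <- function(x, ...) {
  cat("Volume fractions (sum constrained to 1):\n")
  print(round(x$fractions, 6))
  cat(sprintf("  residual norm: %.3g%s\n", x$residual_norm,
              if (x$outside_unit_interval) "  [fractions outside [0,1]]" else ""))
  invisible(x)
}

#' Convert LAC to CT number (Hounsfield units)
#'
#' `HU = 1000 * (mu - mu_water) / mu_water` with the water reference taken
#' at the same energy bin and temperature. Water maps to 0 HU and vacuum
#' to -1000 HU.
#'
#' @param mu LAC value(s), mm^-1.
#' @param mu_water Positive water reference LAC(s), mm^-1.
#' @return CT number(s) in HU.
#' @export
lac_to_hu <- function(mu, mu_water) {
  if (any(mu_water <= 0)) stop("mu_water must be strictly positive")
  1000 * (mu - mu_water) / mu_water
}

#' Thermal change in CT number
#'
#' First-order model of the CT-number change caused by thermal expansion:
#' `dCT(T) = -(1000 + CT(T0)) * alpha * dT`, where `alpha` is the
#' material-specific volumetric thermal expansion coefficient (per degC).
#' Heating expands the material, lowers its density and hence its
#' attenuation.
#'
#' @param ct_at_t0 CT number at the baseline temperature (HU).
#' @param alpha Thermal expansion coefficient (1/degC).
#' @param delta_t Temperature change from baseline (degC).
#' @return Predicted CT-number change (HU).
#' @export
predict_delta_ct <- function(ct_at_t0, alpha, delta_t) {
  stopifnot(is.finite(ct_at_t0), is.finite(alpha), is.finite(delta_t))
  -(1000 + ct_at_t0) * alpha * delta_t
}

#' Fit per-bin thermal sensitivity of a series
#'
#' Ordinary least-squares line of LAC against temperature per energy bin.
#' The slope is the thermal sensitivity in mm^-1 per degC (convert through
#' [lac_to_hu()] for HU per degC); the intercept is evaluated at the series
#' baseline temperature.
#'
#' @param series A [thermal_series()] with at least 3 temperatures.
#' @return An object of class `sensitivity_fit`: `slope_per_bin`,
#'   `intercept_per_bin` (LAC at the baseline temperature), `r2_per_bin`.
#' @export
fit_thermal_sensitivity <- function(series) {
  stopifnot(inherits(series, "thermal_series"))
  if (length(series$temperatures_C) < 3L)
    stop("insufficient data: need at least 3 temperatures")
  tt <- series$temperatures_C - series$baseline_C
  nb <- ncol(series$mu)
  slope <- intercept <- r2 <- numeric(nb)
  for (b in seq_len(nb)) {
    fit <- stats::lm(series$mu[, b] ~ tt)
    slope[b] <- stats::coef(fit)[2]
    intercept[b] <- stats::coef(fit)[1]
    ss_tot <- sum((series$mu[, b] - mean(series$mu[, b]))^2)
    r2[b] <- if (ss_tot <= .Machine$double.eps) 1
             else min(max(1 - sum(stats::residuals(fit)^2) / ss_tot, 0), 1)
  }
  structure(list(slope_per_bin = slope, intercept_per_bin = intercept,
                 r2_per_bin = r2, material = series$material,
                 baseline_C = series$baseline_C),
            class = "sensitivity_fit")
}

#' Linear mixture thermal model
#'
#' The non-learned baseline: assuming each base is linear in temperature,
#' a volumetric mixture would have slope `alpha' = sum(V_i alpha_i)` and
#' offset `beta' = sum(V_i mu_i(T0))` per bin. Real thermal sensitivity
#' depends non-linearly on composition (intermolecular bonding), so this
#' model systematically misses for mixtures — the motivation for the
#' learned regressor.
#'
#' @param fractions Numeric fractions (or a `volume_fractions` object)
#'   aligned to `fits`.
#' @param fits List of [fit_thermal_sensitivity()] results, one per base.
#' @return List with `alpha_prime` and `beta_prime`, 4-vectors.
#' @export
linear_mixture_thermal_model <- function(fractions, fits) {
  if (inherits(fractions, "volume_fractions")) fractions <- fractions$fractions
  fractions <- as.numeric(fractions)
  if (length(fractions) != length(fits))
    stop("fractions must align with fits")
  S <- vapply(fits, `[[`, numeric(length(fits[[1]]$slope_per_bin)), "slope_per_bin")
  B <- vapply(fits, `[[`, numeric(length(fits[[1]]$intercept_per_bin)), "intercept_per_bin")
  list(alpha_prime = drop(S %*% fractions),
       beta_prime = drop(B %*% fractions))
}
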