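#' Write and read projection frames as 16-bit TIFF with JSON sidecar
#'
#' One single-channel 16-bit TIFF per frame; the sidecar `<file>.json`
#' records geometry, threshold (or bin edge), label, seed and flux so a
#' frame set is self-describing.
#'
#' @param counts Count matrix (values must fit in 0..65535).
#' @param path Output path ending in `.tif`.
#' @param meta Named list stored in the sidecar.
#' @return `write_frame_tiff`: `path`, invisibly. `read_frame_tiff`: list
#'   with `counts` and `meta`.
#' @export
write_frame_tiff <- function(counts, path, meta = list()) {
  counts <- round(as.matrix(counts))
  if (any(counts < 0) || any(counts > 65535))
    stop("counts must fit in the 16-bit range 0..65535")
  tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(sprintf("missing sidecar: %s", sidecar))
  list(counts = m, meta = jsonlite::read_json(sidecar, simplifyVector = TRUE))
}

#' Write and read thermal series as CSV
#'
#' Long format: one row per (material, temperature, bin) with columns
#' material, temperature_C, bin_lo_kev, bin_hi_kev, mu_mm1.
#'
#' @param series A [thermal_series()] or list of them.
#' @param path CSV path.
#' @return `write_series_csv`: `path`, invisibly. `read_series_csv`: a
#'   named list of [thermal_series()].
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "thermal_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    lo <- utils::head(s$binning$edges_kev, -1)
    hi <- s$binning$edges_kev[-1]
    nb <- s$binning$n_bins
    data.frame(material = s$material,
               temperature_C = rep(s$temperatures_C, each = nb),
               bin_lo_kev = rep(lo, length(s$temperatures_C)),
               bin_hi_kev = rep(hi, length(s$temperatures_C)),
               mu_mm1 = as.vector(t(s$mu)),
               baseline_C = s$baseline_C)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path)
  out <- lapply(split(d, d$material), function(g) {
    edges <- sort(unique(c(g$bin_lo_kev, g$bin_hi_kev)))
    binning <- energy_binning(edges)
    temps <- sort(unique(g$temperature_C))
    mu <- matrix(NA_real_, length(temps), binning$n_bins)
    for (i in seq_along(temps)) {
      gi <- g[g$temperature_C == temps[i], ]
      mu[i, ] <- gi$mu_mm1[order(gi$bin_lo_kev)]
    }
    thermal_series(g$material[1], temps, mu, baseline_C = g$baseline_C[1],
                   binning = binning)
  })
  out[unique(d$material)]
}

#' Write a LAC measurement table as CSV
#'
#' One row per (material, temperature, bin): mu, variance and LOI count.
#'
#' @param rows Data frame with columns material, temperature_C,
#'   bin_lo_kev, bin_hi_kev, mu_mm1, var, n_loi.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_lac_csv <- function(rows, path) {
  need <- c("material", "temperature_C", "bin_lo_kev", "bin_hi_kev",
            "mu_mm1", "var", "n_loi")
  if (!all(need %in% names(rows))) stop("missing LAC table columns")
  utils::write.csv(rows[need], path, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' A single configuration object driving simulation, extraction and
#' training; round-trips losslessly through YAML.
#'
#' @param geometry A [phantom_geometry()].
#' @param binning An [energy_binning()].
#' @param law A [sensitivity_law()].
#' @param regressor A [regressor_spec()].
#' @param n_per_material Training rows per base material.
#' @param t_range Training temperature range (degC).
#' @param noise_sd_rel Relative Gaussian input-noise SD.
#' @param flux_per_bin Incident counts per pixel per bin for scenes.
#' @param scene_noise Poisson noise in simulated scenes.
#' @param seed Master integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(geometry = phantom_geometry(),
                       binning = energy_binning(),
                       law = sensitivity_law(),
                       regressor = regressor_spec(),
                       n_per_material = 333L,
                       t_range = c(33, 90),
                       noise_sd_rel = 0.005,
                       flux_per_bin = 12000,
                       scene_noise = TRUE,
                       seed = 1L) {
  structure(list(geometry = geometry, binning = binning, law = law,
                 regressor = regressor,
                 n_per_material = as.integer(n_per_material),
                 t_range = as.numeric(t_range),
                 noise_sd_rel = noise_sd_rel,
                 flux_per_bin = flux_per_bin,
                 scene_noise = isTRUE(scene_noise),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#' @param config A [run_config()].
#' @param path YAML path.
#' @return `save_config`: `path`, invisibly. `load_config`: the
#'   [run_config()].
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- list(
    geometry = unclass(config$geometry),
    binning = list(edges_kev = config$binning$edges_kev),
    law = unclass(config$law),
    regressor = unclass(config$regressor)[c("layer_sizes", "learning_rate",
                                            "split", "max_epochs", "seed",
                                            "output_relu", "init")],
    n_per_material = config$n_per_material,
    t_range = config$t_range,
    noise_sd_rel = config$noise_sd_rel,
    flux_per_bin = config$flux_per_bin,
    scene_noise = config$scene_noise,
    seed = config$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  o <- yaml::read_yaml(path)
  run_config(
    geometry = do.call(phantom_geometry, o$geometry),
    binning = energy_binning(o$binning$edges_kev),
    law = do.call(sensitivity_law, o$law),
    regressor = do.call(regressor_spec, o$regressor),
    n_per_material = o$n_per_material,
    t_range = o$t_range,
    noise_sd_rel = o$noise_sd_rel,
    flux_per_bin = o$flux_per_bin,
    scene_noise = o$scene_noise,
    seed = o$seed)
}
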