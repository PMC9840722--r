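#' Self-consistent acquisition geometry
#'
#' The printed setup values (254 mm phantom, 70.4 mm detector,
#' magnification 1.23) cannot hold simultaneously: the phantom shadow
#' would overfill the detector. This helper keeps the source distances and
#' pixel pitch but uses a 25.41 mm phantom side — 462 pixel pitches, so in
#' a parallel-beam check the phantom edges land exactly on pixel
#' boundaries — whose magnified shadow fits comfortably on the detector.
#'
#' @param detector_rows Number of detector rows (232 keeps the default LOI
#'   rows 200-209 available while staying light to simulate).
#' @param detector_cols Number of detector columns.
#' @return A [phantom_geometry()].
#' @export
consistent_geometry <- function(detector_rows = 232L, detector_cols = 1280L) {
  phantom_geometry(side_length_mm = 462 * 0.055,
                   detector_shape = c(detector_rows, detector_cols))
}

#' Simulate a complete synthetic dataset
#'
#' Writes thermal-series CSVs for the three base materials and the two
#' test materials, a YAML copy of the configuration, and (optionally) one
#' simulated phantom scene — eight threshold TIFF frames with JSON
#' sidecars — per material at a mid-range temperature.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param scenes Write TIFF phantom scenes as well as series CSVs.
#' @return Invisibly, a list with the written series, scene file paths and
#'   the config.
#' @export
run_simulate <- function(config = run_config(), out_dir, scenes = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bases <- default_base_set(config$law, noise_sd_rel = 0, seed = config$seed)
  tests <- make_test_materials(config$law, seed = config$seed)
  all_series <- c(bases$bases, tests)
  for (s in all_series)
    write_series_csv(s, file.path(out_dir, paste0(s$material, ".csv")))
  save_config(config, file.path(out_dir, "config.yaml"))
  scene_files <- character(0)
  if (scenes) {
    frames_dir <- file.path(out_dir, "frames")
    dir.create(frames_dir, showWarnings = FALSE)
    for (s in all_series) {
      tmid <- stats::median(s$temperatures_C)
      scene <- make_phantom_scene(config$geometry, s, tmid,
                                  flux_per_bin = config$flux_per_bin,
                                  noise = config$scene_noise,
                                  seed = config$seed)
      for (label in c("empty", "filled")) {
        for (thr in names(scene$thresholds[[label]])) {
          f <- file.path(frames_dir,
                         sprintf("%s_T%g_%s_%s.tif", s$material, tmid, label, thr))
          write_frame_tiff(scene$thresholds[[label]][[thr]], f,
                           meta = list(material = s$material,
                                       temperature_C = tmid,
                                       label = label,
                                       threshold_kev = as.numeric(sub("t", "", thr)),
                                       flux_per_bin = config$flux_per_bin,
                                       seed = scene$seed,
                                       geometry = unclass(config$geometry)))
          scene_files <- c(scene_files, f)
        }
      }
    }
  }
  invisible(list(series = all_series, scene_files = scene_files,
                 config = config))
}

#' Extract LACs from a directory of simulated frames
#'
#' Groups threshold frames by (material, temperature) via their JSON
#' sidecars, forms energy bins by threshold subtraction, runs the full
#' line-of-interest extraction chain over `n_loi` adjacent rows, and
#' writes one CSV row per (material, temperature, bin) with the mean LAC,
#' its inter-LOI variance and the LOI count.
#'
#' @param frames_dir Directory containing `*.tif` + `*.tif.json` pairs
#'   written by [run_simulate()].
#' @param out_csv Output CSV path.
#' @param center_row,n_loi LOI parameters (see [lac_with_variance()]).
#' @param binning An [energy_binning()].
#' @return Invisibly, the LAC table data.frame.
#' @export
run_extract <- function(frames_dir, out_csv, center_row = 200L, n_loi = 10L,
                        binning = energy_binning()) {
  files <- list.files(frames_dir, pattern = "\\.tif$", full.names = TRUE)
  if (length(files) == 0L) stop("no TIFF frames found in ", frames_dir)
  frames <- lapply(files, read_frame_tiff)
  key <- vapply(frames, function(f)
    paste(f$meta$material, f$meta$temperature_C, sep = "@"), character(1))
  rows <- list()
  for (k in unique(key)) {
    grp <- frames[key == k]
    meta <- grp[[1]]$meta
    geometry <- do.call(phantom_geometry, meta$geometry)
    pick <- function(label, thr) {
      hit <- which(vapply(grp, function(f)
        f$meta$label == label && f$meta$threshold_kev == thr, logical(1)))
      if (length(hit) != 1L)
        stop(sprintf("expected one %s frame at threshold %g for %s", label, thr, k))
      grp[[hit]]$counts
    }
    bins <- list(
      empty = counts_to_bins(list(pick("empty", 8), pick("empty", 45)),
                             list(pick("empty", 33), pick("empty", 60)),
                             binning)$bins,
      filled = counts_to_bins(list(pick("filled", 8), pick("filled", 45)),
                              list(pick("filled", 33), pick("filled", 60)),
                              binning)$bins)
    meas <- lac_with_variance(bins$filled, bins$empty, geometry,
                              center_row = center_row, n_loi = n_loi)
    lo <- utils::head(binning$edges_kev, -1)
    rows[[k]] <- data.frame(material = meta$material,
                            temperature_C = meta$temperature_C,
                            bin_lo_kev = lo,
                            bin_hi_kev = binning$edges_kev[-1],
                            mu_mm1 = meas$mu_per_bin,
                            var = meas$var_per_bin,
                            n_loi = meas$n_loi)
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  write_lac_csv(tab, out_csv)
  invisible(tab)
}

# features and targets for a test series, baselined at its first measured
# temperature; the baseline row itself is not evaluated
test_series_features <- function(series) {
  t0 <- series$temperatures_C[1]
  mu0 <- series$mu[1, ]
  temps <- series$temperatures_C[-1]
  X <- t(vapply(temps, function(T)
    build_feature(series_lac_at(series, T)$mu_per_bin, mu0),
    numeric(2 * ncol(series$mu))))
  list(features = X, truth = temps, baseline_C = t0)
}

#' Train the regressor and predict the test materials
#'
#' Generates the training set from the base series, trains the
#' 8-4-4-1 regressor, evaluates both test materials with Monte-Carlo
#' confidence intervals, and (optionally) writes the model JSON and a
#' predictions CSV with columns material, truth, t_hat, ci_low, ci_high.
#'
#' @param bases A [base_material_set()] (or named list of
#'   [thermal_series()] for the bases).
#' @param test_series Named list of test [thermal_series()].
#' @param config A [run_config()].
#' @param var_per_bin Per-bin LAC variance for the CI draws; defaults to
#'   the squared training-noise SD on the water baseline.
#' @param out_dir Optional output directory for `model.json` and
#'   `predictions.csv`.
#' @return List with `model`, `predictions` (data.frame), `mae` (named
#'   per test material), `history`.
#' @export
run_train_predict <- function(bases, test_series, config = run_config(),
                              var_per_bin = NULL, out_dir = NULL) {
  if (!inherits(bases, "base_material_set"))
    bases <- base_material_set(bases)
  ts <- generate_training_set(bases,
                              n_per_material = config$n_per_material,
                              t_range = config$t_range,
                              noise_sd_rel = config$noise_sd_rel,
                              seed = config$seed)
  model <- train_regressor(ts, config$regressor)
  if (is.null(var_per_bin)) {
    mu0_w <- series_lac_at(bases$bases[[1]], bases$baseline_C)$mu_per_bin
    var_per_bin <- (config$noise_sd_rel * mu0_w)^2
  }
  preds <- list(); mae <- numeric(0)
  for (nm in names(test_series)) {
    tf <- test_series_features(test_series[[nm]])
    ci <- lapply(seq_along(tf$truth), function(i)
      predict_with_ci(model, tf$features[i, ], var_per_bin,
                      seed = config$seed + i))
    preds[[nm]] <- data.frame(
      material = test_series[[nm]]$material,
      truth = tf$truth,
      t_hat = vapply(ci, `[[`, numeric(1), "t_hat"),
      ci_low = vapply(ci, `[[`, numeric(1), "ci_low"),
      ci_high = vapply(ci, `[[`, numeric(1), "ci_high"))
    mae[nm] <- evaluate_mae(model, tf$features, tf$truth)
  }
  predictions <- do.call(rbind, c(preds, make.row.names = FALSE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_model(model, file.path(out_dir, "model.json"))
    utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
  }
  list(model = model, predictions = predictions, mae = mae,
       history = model$history)
}
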