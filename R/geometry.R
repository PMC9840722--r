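#' Phantom and detector geometry
#'
#' Describes the acquisition geometry: a point X-ray source, a square-section
#' liquid phantom centred on the beam axis, and a flat photon-counting
#' detector behind it. All lengths are millimetres. The defaults mirror a
#' benchtop photon-counting setup (55 um pixel pitch, 256 x 1280 pixels,
#' source-to-centre 278.5 mm, source-to-detector 342.5 mm).
#'
#' Note the default `side_length_mm` of 254 mm is wider than the default
#' detector (1280 x 0.055 = 70.4 mm); for simulations whose phantom shadow
#' must fit on the detector use a smaller side (e.g. 25.4 mm) or a wider
#' detector.
#'
#' @param side_length_mm External side length L of the square phantom
#'   cross-section (mm).
#' @param source_to_center_mm Distance from the source to the phantom centre
#'   (mm).
#' @param source_to_detector_mm Distance from the source to the detector
#'   plane (mm).
#' @param pixel_pitch_mm Detector pixel pitch (mm).
#' @param detector_shape Integer vector `c(rows, columns)`.
#' @return An object of class `phantom_geometry`.
#' @examples
#' g <- phantom_geometry()
#' magnification(g)
#' @export
phantom_geometry <- function(side_length_mm = 254.0,
                             source_to_center_mm = 278.5,
                             source_to_detector_mm = 342.5,
                             pixel_pitch_mm = 0.055,
                             detector_shape = c(256L, 1280L)) {
  if (!is.numeric(side_length_mm) || side_length_mm <= 0)
    stop("invalid geometry: side_length_mm must be > 0")
  if (source_to_center_mm <= 0 || source_to_detector_mm <= 0)
    stop("invalid geometry: distances must be strictly positive")
  if (source_to_detector_mm <= source_to_center_mm)
    stop("invalid geometry: source_to_detector_mm must exceed source_to_center_mm")
  if (pixel_pitch_mm <= 0)
    stop("invalid geometry: pixel_pitch_mm must be > 0")
  detector_shape <- as.integer(detector_shape)
  if (length(detector_shape) != 2L || any(detector_shape < 1L))
    stop("invalid geometry: detector_shape must be two positive integers")
  structure(
    list(side_length_mm = side_length_mm,
         source_to_center_mm = source_to_center_mm,
         source_to_detector_mm = source_to_detector_mm,
         pixel_pitch_mm = pixel_pitch_mm,
         detector_shape = detector_shape),
    class = "phantom_geometry")
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat("Phantom geometry\n")
  cat(sprintf("  phantom side L        : %g mm\n", x$side_length_mm))
  cat(sprintf("  source -> centre      : %g mm\n", x$source_to_center_mm))
  cat(sprintf("  source -> detector    : %g mm\n", x$source_to_detector_mm))
  cat(sprintf("  magnification         : %.4f\n", magnification(x)))
  cat(sprintf("  detector              : %d x %d px, pitch %g mm\n",
              x$detector_shape[1], x$detector_shape[2], x$pixel_pitch_mm))
  invisible(x)
}

#' Geometric magnification of the setup
#'
#' The ratio of the source-to-detector distance to the source-to-object
#' distance. Features at the phantom centre appear on the detector scaled by
#' this factor; the weak-perspective attenuation integral divides profile
#' areas by it to approximate parallel-beam line integrals.
#'
#' @param geometry A [phantom_geometry()].
#' @return Positive scalar magnification.
#' @examples
#' magnification(phantom_geometry()) # 342.5 / 278.5 = 1.23
#' @export
magnification <- function(geometry) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  geometry$source_to_detector_mm / geometry$source_to_center_mm
}

#' Energy binning from threshold edges
#'
#' Photon-counting acquisitions at increasing energy thresholds are
#' subtracted to form contiguous energy bins. The default edges
#' c(8, 33, 45, 60, 100) keV define the four bins 8-33, 33-45, 45-60 and
#' 60-100 keV.
#'
#' @param edges_kev Strictly increasing numeric vector of 5 bin edges (keV).
#' @return An object of class `energy_binning` with `edges_kev`, `n_bins`,
#'   and a `labels` vector such as "8-33".
#' @export
energy_binning <- function(edges_kev = c(8, 33, 45, 60, 100)) {
  if (length(edges_kev) != 5L || any(diff(edges_kev) <= 0))
    stop("edges_kev must be 5 strictly increasing values (4 bins)")
  structure(
    list(edges_kev = as.numeric(edges_kev),
         n_bins = 4L,
         labels = paste(utils::head(edges_kev, -1), edges_kev[-1], sep = "-")),
    class = "energy_binning")
}

#' A single projection frame
#'
#' A 2D array of non-negative photon counts acquired either above a counting
#' threshold or within an energy bin, for the empty or the filled phantom.
#'
#' @param counts Non-negative numeric matrix (rows x columns).
#' @param threshold_kev Lower threshold (or lower bin edge) in keV.
#' @param label Either "empty" or "filled".
#' @param geometry Optional [phantom_geometry()] used to validate the shape.
#' @return An object of class `projection_frame`.
#' @export
projection_frame <- function(counts, threshold_kev, label = c("empty", "filled"),
                             geometry = NULL) {
  label <- match.arg(label)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("projection counts must be non-negative")
  if (!is.null(geometry) &&
      !all(dim(counts) == geometry$detector_shape))
    stop("counts shape does not match geometry detector_shape")
  structure(list(counts = counts, threshold_kev = threshold_kev, label = label),
            class = "projection_frame")
}

# Exact chord lengths of source->pixel rays through the square cross-section.
# Source at origin, beam axis +x, square centred at (R, 0) with half-side h.
# Returns chord length (mm) per detector column; columns whose ray misses the
# square get 0. Vectorised slab intersection.
ray_square_chords <- function(geometry, parallel = FALSE) {
  L <- geometry$side_length_mm
  R <- geometry$source_to_center_mm
  D <- geometry$source_to_detector_mm
  nc <- geometry$detector_shape[2]
  h <- L / 2
  u <- (seq_len(nc) - (nc + 1) / 2) * geometry$pixel_pitch_mm
  if (parallel) {
    # parallel rays along +x at lateral offset u: chord L inside |u| < h
    return(ifelse(abs(u) < h, L, 0))
  }
  # direction (D, u), normalised
  nrm <- sqrt(D^2 + u^2)
  dx <- D / nrm
  dy <- u / nrm
  t0x <- (R - h) / dx
  t1x <- (R + h) / dx
  t0y <- ifelse(dy == 0, -Inf, pmin(-h / dy, h / dy))
  t1y <- ifelse(dy == 0, Inf, pmax(-h / dy, h / dy))
  t0 <- pmax(t0x, t0y)
  t1 <- pmin(t1x, t1y)
  pmax(t1 - t0, 0)
}

#' Simulate an empty/filled projection pair
#'
#' Forward-simulates one empty and one filled frame per energy bin under
#' Beer-Lambert attenuation along exact source-to-pixel rays. Within a
#' detector row the beam is treated as a fan; rows are replicates of the
#' central fan (the profile analysis is one-dimensional). The empty frame
#' carries the unattenuated flux; the filled frame attenuates it by
#' `exp(-mu * chord)` where the chord through the square cross-section is
#' computed analytically. Counts are rounded to integers; optional Poisson
#' noise replaces the rounding.
#'
#' @param geometry A [phantom_geometry()].
#' @param mu_per_bin Non-negative 4-vector of linear attenuation coefficients
#'   (mm^-1), one per energy bin.
#' @param flux_per_bin Positive incident counts per pixel per bin (scalar
#'   recycled to 4).
#' @param noise Logical; apply Poisson counting noise.
#' @param seed Integer seed used when `noise = TRUE`.
#' @param parallel Logical; use parallel rays instead of the diverging fan
#'   (magnification 1), for geometry checks.
#' @param binning An [energy_binning()] supplying bin lower edges.
#' @return List with elements `empty` and `filled`, each a list of 4
#'   [projection_frame()]s (one per bin), plus `chords_mm`, the per-column
#'   chord lengths.
#' @export
simulate_projection_pair <- function(geometry, mu_per_bin,
                                     flux_per_bin = 20000,
                                     noise = FALSE, seed = 1L,
                                     parallel = FALSE,
                                     binning = energy_binning()) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  mu_per_bin <- as.numeric(mu_per_bin)
  if (length(mu_per_bin) != binning$n_bins)
    stop("mu_per_bin must have one value per energy bin")
  if (any(mu_per_bin < 0)) stop("negative mu is outside the physical domain")
  flux_per_bin <- rep_len(as.numeric(flux_per_bin), binning$n_bins)
  if (any(flux_per_bin <= 0)) stop("flux must be strictly positive")

  nr <- geometry$detector_shape[1]
  nc <- geometry$detector_shape[2]
  chords <- ray_square_chords(geometry, parallel = parallel)
  if (noise) set.seed(as.integer(seed))
  lower <- utils::head(binning$edges_kev, -1)

  empty <- filled <- vector("list", binning$n_bins)
  for (b in seq_len(binning$n_bins)) {
    e_row <- rep(flux_per_bin[b], nc)
    f_row <- flux_per_bin[b] * exp(-mu_per_bin[b] * chords)
    e <- matrix(e_row, nr, nc, byrow = TRUE)
    f <- matrix(f_row, nr, nc, byrow = TRUE)
    if (noise) {
      e[] <- stats::rpois(length(e), e)
      f[] <- stats::rpois(length(f), f)
    } else {
      e <- round(e)
      f <- round(f)
    }
    empty[[b]] <- projection_frame(e, lower[b], "empty", geometry)
    filled[[b]] <- projection_frame(f, lower[b], "filled", geometry)
  }
  names(empty) <- names(filled) <- binning$labels
  list(empty = empty, filled = filled, chords_mm = chords)
}

#' Convert threshold acquisitions to energy-bin frames
#'
#' Two paired acquisitions — one counting above 8 and 45 keV, one above 33
#' and 60 keV — are subtracted into the four contiguous bins:
#' bin1 = counts(>=8) - counts(>=33), bin2 = counts(>=33) - counts(>=45),
#' bin3 = counts(>=45) - counts(>=60), bin4 = counts(>=60). Negative
#' differences (possible under counting noise because the two acquisitions
#' are independent exposures) are clipped to zero and counted.
#'
#' @param acq_8_45 List of two count matrices (or `projection_frame`s) at
#'   thresholds 8 and 45 keV, in that order.
#' @param acq_33_60 List of two count matrices at thresholds 33 and 60 keV.
#' @param binning An [energy_binning()].
#' @return List with `bins` (4 count matrices named by bin label) and
#'   `n_clipped` (number of pixels clipped to zero).
#' @export
counts_to_bins <- function(acq_8_45, acq_33_60, binning = energy_binning()) {
  as_mat <- function(x) if (inherits(x, "projection_frame")) x$counts else as.matrix(x)
  c8 <- as_mat(acq_8_45[[1]]); c45 <- as_mat(acq_8_45[[2]])
  c33 <- as_mat(acq_33_60[[1]]); c60 <- as_mat(acq_33_60[[2]])
  dims <- list(dim(c8), dim(c33), dim(c45), dim(c60))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("threshold frames must share the same shape")
  bins <- list(c8 - c33, c33 - c45, c45 - c60, c60)
  n_clipped <- sum(vapply(bins, function(m) sum(m < 0), numeric(1)))
  if (n_clipped > 0) {
    warning(sprintf("%d negative bin counts clipped to zero", n_clipped))
    bins <- lapply(bins, function(m) pmax(m, 0))
  }
  names(bins) <- binning$labels
  list(bins = bins, n_clipped = n_clipped)
}
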