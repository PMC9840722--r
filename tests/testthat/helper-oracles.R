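# Independent oracles used only by tests.

# Brute-force ray-marching chord length through the square cross-section,
# independent of the analytic slab intersection: sample points along each
# source->pixel ray at a fixed step and accumulate the in-square indicator.
ray_march_chords <- function(geometry, step = 0.005, parallel = FALSE) {
  L <- geometry$side_length_mm
  R <- geometry$source_to_center_mm
  D <- geometry$source_to_detector_mm
  nc <- geometry$detector_shape[2]
  h <- L / 2
  u <- (seq_len(nc) - (nc + 1) / 2) * geometry$pixel_pitch_mm
  tgrid <- seq(0, D + abs(max(u)) + L, by = step)
  vapply(seq_len(nc), function(j) {
    if (parallel) {
      px <- tgrid
      py <- rep(u[j], length(tgrid))
    } else {
      nrm <- sqrt(D^2 + u[j]^2)
      px <- tgrid * D / nrm
      py <- tgrid * u[j] / nrm
    }
    inside <- abs(px - R) < h & abs(py) < h
    step * sum(inside)
  }, numeric(1))
}

# Reference two-stage filter (sliding mean over 5 then median over 7 with
# truncated windows), written as explicit loops, independent of the
# zoo-based implementation.
ref_two_stage_filter <- function(x) {
  n <- length(x)
  trunc_apply <- function(v, w, f) {
    half <- (w - 1) %/% 2
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      out[i] <- f(v[lo:hi])
    }
    out
  }
  trunc_apply(trunc_apply(x, 5, mean), 7, median)
}

# Small self-consistent geometry for fast simulation tests: the LOI rows
# sit at 4..13.
test_geometry <- function(rows = 16L, cols = 1280L) {
  consistent_geometry(detector_rows = rows, detector_cols = cols)
}
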