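test_that("magnification is the detector-to-object distance ratio", {
  expect_equal(round(magnification(phantom_geometry()), 2), 1.23)
  g_eq <- phantom_geometry(source_to_center_mm = 100,
                           source_to_detector_mm = 100 + 1e-9)
  expect_equal(magnification(g_eq), 1.0, tolerance = 1e-9)
  g <- phantom_geometry(source_to_center_mm = 100, source_to_detector_mm = 250)
  expect_equal(magnification(g), 2.5)
})

test_that("invalid geometries are rejected", {
  expect_error(phantom_geometry(side_length_mm = -1), "side_length")
  expect_error(phantom_geometry(source_to_center_mm = -5), "positive")
  expect_error(phantom_geometry(source_to_center_mm = 400,
                                source_to_detector_mm = 300), "exceed")
  expect_error(phantom_geometry(pixel_pitch_mm = 0), "pitch")
  expect_error(energy_binning(c(8, 33, 45, 60)), "5 strictly increasing")
  expect_error(energy_binning(c(8, 45, 33, 60, 100)), "increasing")
})

test_that("vacuum phantom projects identically empty and filled", {
  g <- test_geometry(rows = 4L, cols = 256L)
  pair <- simulate_projection_pair(g, c(0, 0, 0, 0))
  for (b in 1:4)
    expect_identical(pair$filled[[b]]$counts, pair$empty[[b]]$counts)
})

test_that("a single ray obeys Beer-Lambert on its chord", {
  g <- test_geometry(rows = 4L, cols = 256L)
  mu <- 0.02
  pair <- simulate_projection_pair(g, rep(mu, 4), flux_per_bin = 1e6)
  j <- 128  # near-central column
  chord <- pair$chords_mm[j]
  expect_gt(chord, 0)
  ratio <- pair$filled[[1]]$counts[1, j] / pair$empty[[1]]$counts[1, j]
  expect_equal(ratio, exp(-mu * chord), tolerance = 1e-5)
})

test_that("analytic chords and simulated counts match a ray-marching oracle", {
  g <- test_geometry(rows = 2L, cols = 320L)
  oracle <- ray_march_chords(g, step = 0.005)
  analytic <- simulate_projection_pair(g, c(0.05, 0.03, 0.02, 0.02),
                                       flux_per_bin = 2e4)
  hit <- oracle > 1  # interior of the shadow
  expect_gt(sum(hit), 100)
  expect_lt(max(abs(analytic$chords_mm[hit] - oracle[hit])), 0.01)
  # per-pixel count agreement within 0.1%
  mu <- 0.05
  counts_oracle <- 2e4 * exp(-mu * oracle)
  counts_sim <- analytic$filled[[1]]$counts[1, ]
  expect_lt(max(abs(counts_sim - counts_oracle) / counts_oracle), 0.001)
})

test_that("chords are symmetric about the centre column and filled <= empty", {
  g <- test_geometry(rows = 2L, cols = 400L)
  pair <- simulate_projection_pair(g, c(0.05, 0.03, 0.02, 0.015))
  ch <- pair$chords_mm
  expect_equal(ch, rev(ch), tolerance = 1e-9)
  for (b in 1:4)
    expect_true(all(pair$filled[[b]]$counts <= pair$empty[[b]]$counts))
  expect_error(simulate_projection_pair(g, c(-0.01, 0, 0, 0)), "negative mu")
})

test_that("threshold subtraction recovers per-bin counts", {
  mk <- function(v) matrix(v, 2, 3)
  res <- counts_to_bins(list(mk(1000), mk(400)), list(mk(700), mk(100)))
  expect_equal(unname(res$bins[[1]]), mk(300))
  expect_equal(unname(res$bins[[2]]), mk(300))
  expect_equal(unname(res$bins[[3]]), mk(300))
  expect_equal(unname(res$bins[[4]]), mk(100))
  expect_identical(res$n_clipped, 0)

  # monochromatic 50 keV beam: counted above 8, 33 and 45 but not 60
  res2 <- counts_to_bins(list(mk(500), mk(500)), list(mk(500), mk(0)))
  expect_true(all(res2$bins[["45-60"]] == 500))
  expect_true(all(res2$bins[["8-33"]] == 0) && all(res2$bins[["33-45"]] == 0) &&
                all(res2$bins[["60-100"]] == 0))

  expect_error(counts_to_bins(list(mk(10), matrix(1, 3, 3)),
                              list(mk(1), mk(1))), "shape")
  expect_warning(res3 <- counts_to_bins(list(mk(10), mk(8)), list(mk(12), mk(2))),
                 "clipped")
  expect_true(all(res3$bins[[1]] == 0) && res3$n_clipped == 6)
})

test_that("bin frames sum to the open threshold and recover binned flux", {
  g <- test_geometry(rows = 4L, cols = 256L)
  s <- make_base_series(cacl2_material(50))
  scene <- make_phantom_scene(g, s, 48, noise = FALSE)
  bf <- scene_bin_frames(scene)
  for (side in c("empty", "filled")) {
    total <- Reduce(`+`, bf[[side]])
    expect_equal(total, scene$thresholds[[side]]$t8)
  }
  # with noise, thresholded-then-binned counts match per-bin flux within
  # Poisson error on the open field
  sceneN <- make_phantom_scene(g, s, 48, noise = TRUE, seed = 11,
                               flux_per_bin = 12000)
  bfN <- scene_bin_frames(sceneN)
  npx <- length(bfN$empty[[1]])
  for (b in 1:4) {
    m <- mean(bfN$empty[[b]])
    # threshold differences carry the variance of both acquisitions
    expect_lt(abs(m - 12000), 5 * sqrt(7 * 12000 / npx))
  }
})
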