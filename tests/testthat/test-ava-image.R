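test_that("preprocessing inverts and normalises; constant frames degenerate to zeros", {
  m <- matrix(0.85, 32, 32); m[10:15, 10:15] <- 0.15  # dark orifice, bright field
  g <- preprocess_frame(m)
  expect_equal(range(g), c(0, 1))
  expect_true(all(g[10:15, 10:15] == 1))  # orifice now brightest
  rgb <- array(1, dim = c(16, 16, 3))
  expect_warning(g2 <- preprocess_frame(rgb), "constant")
  expect_true(all(g2 == 0))
  # inverting twice is the identity up to normalisation
  g3 <- preprocess_frame(1 - m)
  expect_equal(g3, 1 - g, tolerance = 1e-12)
})

test_that("mask clean-up fills holes, removes specks, and applies the circular ROI", {
  g <- matrix(0, 128, 128)
  g[40:80, 40:80] <- 1          # ~1680 px object
  g[60:62, 60:62] <- 0          # interior hole
  g[5:6, 5:6] <- 1              # 4-px speck far outside the valve circle? keep inside
  g[20:21, 64:65] <- 1          # 4-px speck inside circle
  cfg <- ava_image_config(threshold = 0.5, min_object_px = 50,
                          closing_radius_px = 0,
                          valve_center = c(64, 64), valve_radius = 60)
  m <- binarize_and_clean(g, cfg)
  expect_true(all(m[60:62, 60:62]))       # hole filled
  expect_false(any(m[20:21, 64:65]))      # speck removed
  expect_equal(sum(m), 41^2)
  rr <- row(m) - 64; cc <- col(m) - 64
  expect_true(all(m[rr^2 + cc^2 > 60^2] == 0))  # outside circle always zero
})

test_that("two largest components are summed and converted to cm^2", {
  m <- matrix(0, 120, 220)
  m[10:49, 10:34] <- 1     # 1000 px
  m[60:89, 50:69] <- 1     # 600 px
  m[100:104, 100:109] <- 1 # 50 px
  expect_equal(two_largest_area(m, 100), 0.16)
  expect_equal(two_largest_area(matrix(0, 10, 10), 100), 0)
  m2 <- matrix(0, 120, 120); m2[11:60, 11:90] <- 1  # single 4000 px component
  expect_equal(two_largest_area(m2, 100), 0.40)
})

test_that("8-connectivity joins diagonally touching lobes", {
  m <- matrix(0, 20, 20)
  m[5:8, 5:8] <- 1
  m[9:12, 9:12] <- 1   # touches only diagonally
  expect_equal(two_largest_area(m, 10), 32 / 100)
  # with a third separate region, the two largest are picked
  m[16:17, 16:19] <- 1
  expect_equal(two_largest_area(m, 10), (32 + 8) / 100)
})

test_that("video AVA round-trips the rendered ground truth within 2%", {
  areas <- c(0.785, 0.45, 0.25)
  fs <- render_endoscope_frames(areas, px_per_cm = 130, valve_radius = 160,
                                shape = c(360, 360), noise_sd = 0)
  out <- ava_series_with_bounds(fs, ava_image_config(threshold = 0.5))
  expect_equal(out$area, fs$true_area_cm2, tolerance = 0.02)
  expect_true(all(out$area_lower <= out$area + 1e-12))
  expect_true(all(out$area <= out$area_upper + 1e-12))
})

test_that("threshold envelopes are monotone and a blank stack yields zeros", {
  fs <- render_endoscope_frames(c(0.6, 0.3), px_per_cm = 120, valve_radius = 120,
                                shape = c(280, 280), noise_sd = 0.03, seed = 5)
  g <- preprocess_frame(fs$frames[[1]])
  cfg <- ava_image_config(threshold = 0.5, valve_center = fs$valve_center,
                          valve_radius = fs$valve_radius, px_per_cm = fs$px_per_cm)
  areas <- vapply(c(0.35, 0.45, 0.55, 0.65), function(th) {
    c2 <- cfg; c2$threshold <- th
    two_largest_area(binarize_and_clean(g, c2), fs$px_per_cm)
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-12))  # non-increasing in threshold
  blank <- render_endoscope_frames(c(0, 0), px_per_cm = 120, valve_radius = 120,
                                   shape = c(280, 280), noise_sd = 0)
  suppressWarnings(out0 <- ava_series_with_bounds(blank,
                                                  ava_image_config(threshold = 0.5)))
  expect_true(all(out0$area == 0))
})

test_that("noisy stacks recover the cycle maximum AVA within 5%", {
  t_grid <- seq(0, 0.5, by = 0.05)
  truth <- 0.7 * pmax(0, sin(pi * t_grid / 0.5))
  fs <- render_endoscope_frames(truth, timestamps = t_grid, px_per_cm = 150,
                                valve_radius = 160, shape = c(360, 360),
                                noise_sd = 0.05, seed = 4)
  suppressWarnings(out <- ava_series_with_bounds(fs, ava_image_config(threshold = 0.5)))
  expect_equal(max(out$area), max(fs$true_area_cm2), tolerance = 0.05)
  mx <- max_ava_per_cycle(out, 0.55)
  expect_equal(mx$max_area[1], max(out$area))
})

test_that("ava_series enforces the lower <= area <= upper ordering", {
  expect_error(ava_series(1:3, c(1, 2, 3), area_lower = c(2, 2, 2)), "ordering")
  s <- ava_series(1:3, c(1, 2, 3), c(0.9, 1.9, 2.9), c(1.1, 2.1, 3.1))
  expect_s3_class(s, "ava_series")
})
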