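test_that("pressure template repeats exactly across cycles without noise and peaks at dp_peak", {
  bc <- baseline_cycle(noise_sd = 0, n_cycles = 3)
  ens <- segment_cycles(bc$dp, bc$spec$cycle_time)
  expect_equal(ens$cycles[[2]]$value, ens$cycles[[1]]$value, tolerance = 1e-12)
  expect_equal(ens$cycles[[3]]$value, ens$cycles[[1]]$value, tolerance = 1e-12)
  spec60 <- mock_loop_spec("d0", dp_peak = 60, noise_sd = 0)
  pp <- generate_pressure_traces(spec60)
  dp <- pressure_difference(pp$p_lv, pp$p_ao)
  expect_equal(max(dp$value), 60, tolerance = 1e-3)
})

test_that("generators are seed-deterministic and seeds differ", {
  a <- generate_pressure_traces(mock_loop_spec("d0", noise_sd = 0.05, seed = 1))
  b <- generate_pressure_traces(mock_loop_spec("d0", noise_sd = 0.05, seed = 1))
  c <- generate_pressure_traces(mock_loop_spec("d0", noise_sd = 0.05, seed = 2))
  expect_identical(a$p_lv$value, b$p_lv$value)
  expect_false(identical(a$p_lv$value, c$p_lv$value))
  f1 <- render_endoscope_frames(c(0.5), px_per_cm = 100, valve_radius = 80,
                                shape = c(192, 192), noise_sd = 0.05, seed = 7)
  f2 <- render_endoscope_frames(c(0.5), px_per_cm = 100, valve_radius = 80,
                                shape = c(192, 192), noise_sd = 0.05, seed = 7)
  expect_identical(f1$frames[[1]], f2$frames[[1]])
  c1 <- generate_leaflet_cloud(0.5, seed = 3)
  c2 <- generate_leaflet_cloud(0.5, seed = 3)
  expect_identical(c1$points, c2$points)
})

test_that("orifice law gives the hand-converted flow and Bernoulli scaling", {
  tt <- seq(0, 1, by = 1e-3)
  dp40 <- time_trace(tt, rep(40, length(tt)), "mmHg")
  q <- generate_flow_trace(dp40, orifice_area = 1, discharge_coeff = 1)
  expect_equal(q$value[1], 326.6, tolerance = 0.001)  # 40 mmHg = 5332.9 Pa
  dp0 <- time_trace(tt, rep(0, length(tt)), "mmHg")
  expect_true(all(generate_flow_trace(dp0, 1)$value == 0))
  dp80 <- time_trace(tt, rep(80, length(tt)), "mmHg")
  q2 <- generate_flow_trace(dp80, orifice_area = 1, discharge_coeff = 1)
  expect_equal(q2$value / q$value, rep(sqrt(2), length(tt)), tolerance = 1e-12)
  expect_error(generate_flow_trace(dp40, orifice_area = 0), "area")
})

test_that("flow scaling hits the thermodilution stroke volume and is idempotent", {
  bc <- baseline_cycle()
  dp1 <- segment_cycles(bc$dp, 0.8)$cycles[[1]]
  q <- generate_flow_trace(dp1, 1.2, 0.8)
  q_d0 <- scale_flow_to_co(q, 3.2, 75)
  pos <- function(x) time_trace(x$time, pmax(x$value, 0))
  expect_equal(trace_integral(pos(q_d0)), 3200 / 75, tolerance = 1e-6)  # 42.67 mL
  q_d20 <- scale_flow_to_co(q, 5.1, 107)
  expect_equal(trace_integral(pos(q_d20)), 5100 / 107, tolerance = 1e-6)  # 47.66 mL
  q_again <- scale_flow_to_co(q_d0, 3.2, 75)
  expect_equal(attr(q_again, "scale"), 1, tolerance = 1e-9)
})

test_that("pump return inserts exactly the requested negative volume in diastole", {
  bc <- baseline_cycle()
  dp1 <- segment_cycles(bc$dp, 0.8)$cycles[[1]]
  q <- scale_flow_to_co(generate_flow_trace(dp1, 1.2, 0.8), 3.2, 75)
  qr <- add_pump_return(q, 5)
  neg <- time_trace(qr$time, pmin(qr$value, 0))
  expect_equal(trace_integral(neg), -5, tolerance = 0.01)
  # positive-phase samples untouched
  expect_identical(qr$value[q$value > 0], q$value[q$value > 0])
  # net cycle volume decreases by exactly the return volume (trapezoid oracle)
  expect_equal(trace_integral(qr), trace_integral(q) - 5, tolerance = 0.02)
  expect_identical(add_pump_return(q, 0)$value, q$value)
})

test_that("volume bookkeeping holds: positive minus negative phase equals SV - 5 mL", {
  bc <- baseline_cycle()
  dp1 <- segment_cycles(bc$dp, 0.8)$cycles[[1]]
  q <- scale_flow_to_co(generate_flow_trace(dp1, 1.2, 0.8), 3.2, 75)
  qr <- add_pump_return(q, 5)
  vol_pos <- trace_integral(time_trace(qr$time, pmax(qr$value, 0)))
  vol_neg <- trace_integral(time_trace(qr$time, pmin(qr$value, 0)))
  expect_equal(vol_pos - abs(vol_neg), 3200 / 75 - 5, tolerance = 0.1)
})

test_that("rendered frames carry a ground-truth area consistent with pixel counting", {
  fs <- render_endoscope_frames(c(0.785), px_per_cm = 150, valve_radius = 200,
                                shape = c(440, 440), lobe = 0, noise_sd = 0)
  # circular orifice r = 0.5 cm: truth within 2% of pi r^2 at 200 px radius
  expect_equal(fs$true_area_cm2[1], pi * 0.25, tolerance = 0.02)
  # brute-force count of below-field pixels in the noise-free frame
  n_dark <- sum(fs$frames[[1]] < 0.5)
  expect_equal(n_dark / 150^2, fs$true_area_cm2[1], tolerance = 0.02)
  expect_error(render_endoscope_frames(c(50), px_per_cm = 150, valve_radius = 50),
               "larger")
})

test_that("leaflet cloud resolves a known orifice and rejects too-few points", {
  expect_error(generate_leaflet_cloud(0.5, n_points = 100), "minimum")
  cl <- generate_leaflet_cloud(0.5, seed = 2)
  expect_setequal(unique(cl$leaflet_label), 1:3)
  expect_equal(sqrt(sum(cl$axis^2)), 1)
  # zero opening leaves no interior hole
  cl0 <- generate_leaflet_cloud(0, seed = 2)
  res0 <- ava_with_resolution_bounds(cl0, raster_config(150, physical_extent = 3))
  expect_equal(res0$area, 0)
})
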