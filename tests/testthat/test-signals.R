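test_that("cycle segmentation drops partial cycles and averages reduce noise like 1/sqrt(N)", {
  tt <- seq(0, 6.5 * 0.8 - 1e-3, by = 1e-3)
  per <- sin(2 * pi * tt / 0.8)
  ens <- segment_cycles(time_trace(tt, per), 0.8)
  expect_length(ens$cycles, 6)
  expect_equal(ens$cycles[[4]]$value, ens$cycles[[1]]$value, tolerance = 1e-9)
  expect_error(segment_cycles(time_trace(tt[1:900], per[1:900]), 0.8), "2 full")
  # Monte-Carlo oracle: per-sample sd sigma, N cycles -> sd_trace ~ sigma and
  # the cycle-averaged waveform has sd ~ sigma/sqrt(N)
  set.seed(42)
  n_cyc <- 50; n1 <- 400; sigma <- 0.3
  tt2 <- seq_len(n_cyc * n1) * 1e-3
  base <- sin(2 * pi * tt2 / (n1 * 1e-3))
  noisy <- time_trace(tt2, base + rnorm(length(tt2), 0, sigma))
  ens2 <- segment_cycles(noisy, n1 * 1e-3)
  expect_equal(mean(ens2$sd_trace$value), sigma, tolerance = 0.2 * sigma)
  resid <- ens2$mean_trace$value - base[seq_len(n1)]
  expect_equal(sd(resid), sigma / sqrt(n_cyc), tolerance = 0.2 * sigma / sqrt(n_cyc))
})

test_that("pressure difference is exact, antisymmetric, and refuses mismatched grids", {
  tt <- seq(0, 1, by = 1e-2)
  a <- time_trace(tt, sin(tt), "mmHg")
  b <- time_trace(tt, sin(tt) + 40, "mmHg")
  expect_true(all(pressure_difference(a, a)$value == 0))
  expect_equal(pressure_difference(b, a)$value, rep(40, length(tt)))
  expect_equal(pressure_difference(a, b)$value, -pressure_difference(b, a)$value)
  cc <- time_trace(tt + 0.5, sin(tt), "mmHg")
  expect_error(pressure_difference(a, cc), "common")
})

test_that("periodic extension preserves per-cycle integrals and the fundamental frequency", {
  tt <- seq(0, 0.8 - 1e-3, by = 1e-3)
  tmpl <- time_trace(tt, 2 + sin(2 * pi * tt / 0.8))
  expect_equal(periodic_extend(tmpl, 1)$value, tmpl$value)
  ext <- periodic_extend(tmpl, 6)
  expect_length(ext$value, 6 * length(tmpl$value))
  ints <- vapply(0:5, function(k)
    sum(ext$value[k * 800 + 1:800]) * 1e-3, numeric(1))
  expect_equal(ints, rep(ints[1], 6), tolerance = 1e-12)
  # FFT oracle: dominant non-DC frequency of the extension = 1/T
  sp <- Mod(stats::fft(ext$value - mean(ext$value)))
  freqs <- (seq_along(sp) - 1) / (length(ext$value) * 1e-3)
  expect_equal(freqs[which.max(sp[1:2000])], 1 / 0.8, tolerance = 1e-6)
})

test_that("ejection window runs from the pLV crossing to the first negative flow", {
  tt <- seq(0, 0.8, by = 1e-3)
  dp <- ifelse(tt >= 0.1 & tt <= 0.4, 30 * sin(pi * (tt - 0.1) / 0.3), -5)
  p_ao <- time_trace(tt, rep(80, length(tt)))
  p_lv <- time_trace(tt, 80 + dp)
  q <- time_trace(tt, ifelse(tt < 0.42, pmax(dp, 0) * 5, -10))
  w <- ejection_window(q, p_lv, p_ao)
  expect_equal(unname(w[1]), 0.1, tolerance = 2e-3)
  expect_equal(unname(w[2]), 0.42, tolerance = 6e-3)  # one-sample quantisation
  # fallback: flow never negative -> window ends at the dp downward crossing
  q_pos <- time_trace(tt, pmax(dp, 0) * 5)
  w2 <- ejection_window(q_pos, p_lv, p_ao)
  expect_equal(unname(w2[2]), 0.4, tolerance = 2e-3)
  # translation oracle: delaying both traces by tau delays the window by tau
  mk <- function(t0) {
    dpv <- ifelse(tt >= t0 & tt <= t0 + 0.3, 30 * sin(pi * (tt - t0) / 0.3), -5)
    list(q = time_trace(tt, ifelse(tt < t0 + 0.32, pmax(dpv, 0) * 5, -10)),
         lv = time_trace(tt, 80 + dpv), ao = time_trace(tt, rep(80, length(tt))))
  }
  a <- mk(0.10); b <- mk(0.25)
  wa <- ejection_window(a$q, a$lv, a$ao)
  wb <- ejection_window(b$q, b$lv, b$ao)
  expect_equal(unname(wb - wa), c(0.15, 0.15), tolerance = 0.01)
})

test_that("ejection-window statistics match closed forms", {
  tt <- seq(0, 0.5, by = 1e-4)
  w <- c(0.1, 0.35)
  rect <- time_trace(tt, ifelse(tt >= w[1] & tt <= w[2], 200, 0))
  expect_equal(q_mean(rect, w), 200, tolerance = 1e-3)
  expect_equal(stroke_volume(rect, w), 200 * 0.25, tolerance = 0.05)
  half <- time_trace(tt, ifelse(tt >= w[1] & tt <= w[2],
                                300 * sin(pi * (tt - w[1]) / 0.25), 0))
  expect_equal(q_mean(half, w), 2 / pi * 300, tolerance = 0.01)
  expect_equal(stroke_volume(half, w), q_mean(half, w) * 0.25, tolerance = 1e-9)
  expect_error(q_mean(rect, c(0.2, 0.2)), "zero-length")
})

test_that("a trace constructed for a given ejection mean reproduces it", {
  # round-trip against the baseline experimental mean flow value
  tt <- seq(0, 0.8, by = 1e-4)
  w <- c(0.1, 0.38)
  target <- 143
  peak <- target * pi / 2
  q <- time_trace(tt, ifelse(tt >= w[1] & tt <= w[2],
                             peak * sin(pi * (tt - w[1]) / diff(w)), 0))
  expect_equal(q_mean(q, w), 143, tolerance = 0.5)
})

test_that("dp_mean uses only the positive phase and matches the half-sine closed form", {
  tt <- seq(0, 0.28, by = 1e-3)
  expect_equal(dp_mean(time_trace(tt, rep(44, length(tt)))), 44)
  hs <- half_sine_trace(69)
  expect_equal(dp_mean(hs), 2 / pi * 69, tolerance = 0.01)
  # adding a negative diastolic plateau leaves the result unchanged
  tt2 <- seq(0, 0.8, by = 1e-3)
  v2 <- c(69 * sin(pi * tt2[tt2 <= 0.28] / 0.28), rep(-30, sum(tt2 > 0.28)))
  expect_equal(dp_mean(time_trace(tt2, v2)), dp_mean(hs), tolerance = 0.05)
  expect_error(dp_mean(time_trace(tt, rep(-1, length(tt)))), "positive")
})

test_that("inter-cycle statistics and uncertainty bounds are exact", {
  s <- inter_cycle_stats(c(140, 160))
  expect_equal(unname(s["mean"]), 150)
  expect_equal(unname(s["sd"]), sqrt(200), tolerance = 1e-9)  # 14.14, sample sd
  expect_equal(unname(inter_cycle_stats(rep(7, 5))["sd"]), 0)
  b <- uncertainty_bounds(137)
  expect_equal(unname(b), c(123.3, 150.7))
  expect_equal(unname(diff(uncertainty_bounds(55, 0.2))), 2 * 0.2 * 55)
  expect_equal(unname(uncertainty_bounds(10, 0)), c(10, 10))
})

test_that("stroke volume of the scaled baseline flow equals CO/HR", {
  bc <- baseline_cycle()
  dp1 <- segment_cycles(bc$dp, 0.8)$cycles[[1]]
  q <- scale_flow_to_co(generate_flow_trace(dp1, 1.2, 0.8), 3.2, 75)
  qr <- add_pump_return(q, 5)
  lv1 <- segment_cycles(bc$p_lv, 0.8)$cycles[[1]]
  ao1 <- segment_cycles(bc$p_ao, 0.8)$cycles[[1]]
  w <- ejection_window(qr, lv1, ao1)
  expect_equal(stroke_volume(qr, w), 42.7, tolerance = 0.2)
})

test_that("linearity: q_mean and stroke_volume scale linearly in the flow", {
  tt <- seq(0, 0.5, by = 1e-3)
  w <- c(0.05, 0.45)
  q1 <- time_trace(tt, abs(sin(7 * tt)) * 100)
  for (a in c(0.5, 2, 13)) {
    qa <- time_trace(tt, a * q1$value)
    expect_equal(q_mean(qa, w), a * q_mean(q1, w), tolerance = 1e-10)
    expect_equal(stroke_volume(qa, w), a * stroke_volume(q1, w), tolerance = 1e-10)
  }
})

test_that("hemo_summary is invariant to the trace start phase", {
  spec <- mock_loop_spec("d0", noise_sd = 0, n_cycles = 4)
  pp <- generate_pressure_traces(spec)
  dp <- pressure_difference(pp$p_lv, pp$p_ao)
  q <- generate_flow_trace(dp, 1.2, 0.8)
  h1 <- hemo_summary(q, pp$p_lv, pp$p_ao, 0.8)
  # start inside diastole so the ejection window is not split across cycles
  h2 <- hemo_summary(q, pp$p_lv, pp$p_ao, 0.8, start_index = 401L)
  expect_equal(h1$q_mean, h2$q_mean, tolerance = 1e-6)
  expect_equal(h1$dp_mean, h2$dp_mean, tolerance = 1e-6)
})
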