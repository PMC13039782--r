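# Shared synthetic fixtures, generated in code at test time.

# one noise-free baseline-condition cycle of pressures and derived flow
baseline_cycle <- function(noise_sd = 0, n_cycles = 3, seed = 1L) {
  spec <- mock_loop_spec("d0", noise_sd = noise_sd, n_cycles = n_cycles,
                         seed = seed)
  pp <- generate_pressure_traces(spec)
  dp <- pressure_difference(pp$p_lv, pp$p_ao)
  list(spec = spec, p_lv = pp$p_lv, p_ao = pp$p_ao, dp = dp)
}

# a pure half-sine pressure-difference trace (closed-form oracle shapes)
half_sine_trace <- function(peak, duration = 0.28, fs = 1000) {
  tt <- seq(0, duration, by = 1 / fs)
  time_trace(tt, peak * sin(pi * tt / duration), "mmHg")
}

# the small flap benchmark geometry used by the FSI property tests: a
# leaning leaflet (like a partially open valve) whose tip gap responds at
# first order to bending
flap_benchmark_geometry <- function() {
  fsi_channel_geometry(length_m = 0.08, height_m = 0.02, flap_x = 0.03,
                       flap_tip = 0.014, flap_thickness = 0.003,
                       flap_lean = 0.5, nx = 20, ny = 8, refine_flap = 1)
}

# one systolic pulse (half-sine up to t_sys, then a negative diastolic value)
benchmark_pulse <- function(t_end = 0.3, t_sys = 0.16, peak_mmhg = 4,
                            diastolic_mmhg = -1, fs = 1000) {
  tt <- seq(0, t_end, by = 1 / fs)
  v <- ifelse(tt < t_sys, peak_mmhg * sin(pi * tt / t_sys), diastolic_mmhg)
  time_trace(tt, v, "mmHg")
}

benchmark_config <- function(...) {
  fsi_coupling_config(dt = 1e-3, epsilon = 1e-4, max_newton_iters = 60, ...)
}
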