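#' Study conditions of the mock-loop experiments
#'
#' The bench experiments were run at four stepwise dobutamine infusion levels
#' (d0, d5, d10, d20 corresponding to 0, 5, 10, 20 ug/kg/min), each with its
#' own heart rate, thermodilution cardiac output, cycle time, and mean
#' transvalvular pressure drop (different for the non-calcified and calcified
#' valve). These values parameterise the synthetic generators.
#'
#' Note: the tabulated d5 cycle time is 0.76 s while 60/81 bpm = 0.74 s and
#' the simulation protocol quotes 0.75 s; the tabulated value is stored
#' verbatim and the discrepancy is simply carried, not resolved.
#'
#' @return a data.frame with one row per dobutamine condition: `condition`,
#'   `heart_rate` (bpm), `cardiac_output` (L/min), `cycle_time` (s),
#'   `dp_mean_noncalc` and `dp_mean_calc` (mmHg)
#' @export
mock_loop_conditions <- function() {
  data.frame(
    condition       = c("d0", "d5", "d10", "d20"),
    heart_rate      = c(75, 81, 88, 107),
    cardiac_output  = c(3.2, 5.1, 5.5, 5.1),
    cycle_time      = c(0.80, 0.76, 0.70, 0.57),
    dp_mean_noncalc = c(44, 52, 51, 53),
    dp_mean_calc    = c(77, 89, 87, 85),
    stringsAsFactors = FALSE
  )
}

#' Mock-loop generator specification
#'
#' Bundles the parameters of one synthetic mock-loop run. Defaults reproduce
#' the baseline (d0) condition with the non-calcified valve: 75 bpm, 3.2
#' L/min, 0.8 s cycle. The systolic pressure-difference template is a
#' half-sine hump whose amplitude is `dp_peak`; since the mean of a half-sine
#' over its support is 2/pi of its peak, `dp_peak = dp_mean * pi/2` makes the
#' mean transvalvular pressure drop equal the per-condition value.
#'
#' @param condition one of "d0", "d5", "d10", "d20"; fills heart rate,
#'   cardiac output, cycle time and dp_peak from [mock_loop_conditions()]
#' @param valve "non-calcified" or "calcified" (selects the dp_mean column)
#' @param heart_rate beats/min
#' @param cardiac_output L/min
#' @param cycle_time s
#' @param n_cycles number of cardiac cycles to generate
#' @param systolic_fraction fraction of the cycle occupied by the systolic
#'   pressure hump, in (0,1)
#' @param dp_peak peak systolic pressure difference, mmHg
#' @param diastolic_dp diastolic pressure-difference plateau, mmHg (negative:
#'   aortic pressure exceeds ventricular pressure while the valve is closed)
#' @param noise_sd additive Gaussian noise, as a fraction of `dp_peak`
#' @param fs sampling frequency, Hz
#' @param seed integer RNG seed
#' @return an object of class `mock_loop_spec`
#' @export
mock_loop_spec <- function(condition = "d0", valve = "non-calcified",
                           heart_rate = NULL, cardiac_output = NULL,
                           cycle_time = NULL, n_cycles = 6,
                           systolic_fraction = 0.35, dp_peak = NULL,
                           diastolic_dp = -30, noise_sd = 0.02,
                           fs = 1000, seed = 1L) {
  cond <- mock_loop_conditions()
  row <- cond[cond$condition == condition, ]
  if (nrow(row) != 1) stop("unknown condition: ", condition)
  valve <- match.arg(valve, c("non-calcified", "calcified"))
  if (is.null(heart_rate)) heart_rate <- row$heart_rate
  if (is.null(cardiac_output)) cardiac_output <- row$cardiac_output
  if (is.null(cycle_time)) cycle_time <- row$cycle_time
  if (is.null(dp_peak)) {
    dpm <- if (valve == "non-calcified") row$dp_mean_noncalc else row$dp_mean_calc
    dp_peak <- dpm * pi / 2
  }
  spec <- structure(list(
    condition = condition, valve = valve,
    heart_rate = heart_rate, cardiac_output = cardiac_output,
    cycle_time = cycle_time, n_cycles = as.integer(n_cycles),
    systolic_fraction = systolic_fraction, dp_peak = dp_peak,
    diastolic_dp = diastolic_dp, noise_sd = noise_sd,
    fs = fs, seed = as.integer(seed)
  ), class = "mock_loop_spec")
  validate_mock_loop_spec(spec)
  spec
}

validate_mock_loop_spec <- function(spec) {
  with(spec, {
    if (!(cycle_time > 0)) stop("cycle_time must be > 0")
    if (!(n_cycles >= 1)) stop("n_cycles must be >= 1")
    if (!(systolic_fraction > 0 && systolic_fraction < 1))
      stop("systolic_fraction must lie in (0,1)")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (!(heart_rate > 0 && cardiac_output > 0)) stop("HR and CO must be > 0")
    if (diastolic_dp > 0) stop("diastolic_dp must be <= 0 (plateau below zero)")
  })
  invisible(spec)
}

#' @export
print.mock_loop_spec <- function(x, ...) {
  cat(sprintf(
    "<mock_loop_spec> %s / %s: HR %g bpm, CO %g L/min, T %g s, %d cycles\n",
    x$condition, x$valve, x$heart_rate, x$cardiac_output, x$cycle_time,
    x$n_cycles))
  cat(sprintf("  dp_peak %.1f mmHg, diastolic %.1f mmHg, noise_sd %g, seed %d\n",
              x$dp_peak, x$diastolic_dp, x$noise_sd, x$seed))
  invisible(x)
}

# Noise-free single-cycle pressure-difference template (mmHg) on the sample
# grid: half-sine systolic hump over systolic_fraction * T, negative plateau
# over the rest of the cycle.
dp_template <- function(spec) {
  n <- round(spec$cycle_time * spec$fs)
  tt <- (seq_len(n) - 1) / spec$fs
  t_sys <- spec$systolic_fraction * spec$cycle_time
  ifelse(tt < t_sys,
         spec$dp_peak * sin(pi * tt / t_sys),
         spec$diastolic_dp)
}

#' Generate synthetic left-ventricular and aortic pressure traces
#'
#' Builds one noise-free template cycle (half-sine systolic pressure hump
#' followed by a constant negative diastolic plateau, mimicking the measured
#' transvalvular pressure-difference shape), repeats it over `n_cycles`, and
#' adds i.i.d. Gaussian noise per sample to both channels. The aortic channel
#' carries a smooth dicrotic baseline so both traces look physiological; the
#' difference pLV - pao equals the template exactly when `noise_sd = 0`.
#'
#' @param spec a [mock_loop_spec()]
#' @return a list with `p_lv` and `p_ao`, both `time_trace`s in mmHg
#' @export
generate_pressure_traces <- function(spec) {
  validate_mock_loop_spec(spec)
  n1 <- round(spec$cycle_time * spec$fs)
  n <- n1 * spec$n_cycles
  tt <- (seq_len(n) - 1) / spec$fs
  dp1 <- dp_template(spec)
  dp <- rep(dp1, spec$n_cycles)
  # aortic baseline: mean 90 mmHg with a gentle cyclic swing
  phase <- 2 * pi * (tt %% spec$cycle_time) / spec$cycle_time
  p_ao <- 90 + 10 * sin(phase) + 3 * sin(2 * phase)
  p_lv <- p_ao + dp
  if (spec$noise_sd > 0) {
    rng <- local_seed(spec$seed)
    on.exit(rng(), add = TRUE)
    sd <- spec$noise_sd * spec$dp_peak
    p_lv <- p_lv + stats::rnorm(n, 0, sd)
    p_ao <- p_ao + stats::rnorm(n, 0, sd)
  }
  list(p_lv = time_trace(tt, p_lv, "mmHg"),
       p_ao = time_trace(tt, p_ao, "mmHg"))
}

# Set the RNG seed locally; returns a restorer function.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Synthetic transvalvular flow from a pressure-difference trace
#'
#' Quasi-static orifice (Bernoulli) law: Q = Cd * A * sqrt(2 max(dp,0) / rho)
#' with water density rho = 1000 kg/m^3. This is deliberately simple test
#' scaffolding with an analytic ground truth, not a haemodynamic model: it
#' gives the downstream signal statistics closed forms to be checked against.
#'
#' @param dp pressure-difference `time_trace` in mmHg
#' @param orifice_area valve opening area, cm^2
#' @param discharge_coeff dimensionless discharge coefficient
#' @return flow `time_trace` in mL/s (zero wherever dp <= 0)
#' @export
generate_flow_trace <- function(dp, orifice_area, discharge_coeff = 0.8) {
  if (!(orifice_area > 0)) stop("orifice_area must be > 0")
  dp_pa <- mmhg_to_pa(pmax(dp$value, 0))
  q_m3s <- discharge_coeff * (orifice_area * 1e-4) * sqrt(2 * dp_pa / 1000)
  time_trace(dp$time, q_m3s * 1e6, "mL/s")
}

#' Scale a one-cycle flow trace to a measured cardiac output
#'
#' Multiplies the trace by the single factor that makes the time-integral of
#' its positive phase over the cycle equal the stroke volume CO/HR, mirroring
#' how the bench flow curves were scaled to the thermodilution cardiac output.
#'
#' @param q one-cycle flow `time_trace` in mL/s
#' @param cardiac_output L/min
#' @param heart_rate beats/min
#' @return the rescaled `time_trace`; the scale factor is attached as
#'   attribute `"scale"`
#' @export
scale_flow_to_co <- function(q, cardiac_output, heart_rate) {
  if (!(cardiac_output > 0 && heart_rate > 0)) stop("CO and HR must be > 0")
  sv_target <- cardiac_output / heart_rate * 1000  # mL per beat
  qpos <- time_trace(q$time, pmax(q$value, 0), q$units)
  sv_now <- trace_integral(qpos)
  if (sv_now <= 0) stop("cannot scale: no net positive flow in trace")
  s <- sv_target / sv_now
  out <- time_trace(q$time, q$value * s, q$units)
  attr(out, "scale") <- s
  out
}

#' Append a pump-return (negative flow) lobe in diastole
#'
#' The bench gear pump was driven with a small negative flow whose integral
#' was 5 mL to restore realistic proximal pressures. This inserts a negative
#' half-sine lobe with time-integral `-return_volume` into the longest
#' zero-flow (diastolic) window of the trace; positive-phase samples are
#' untouched.
#'
#' @param q flow `time_trace` in mL/s with a zero-flow diastolic segment
#' @param return_volume mL, default 5
#' @return the modified `time_trace`
#' @export
add_pump_return <- function(q, return_volume = 5) {
  if (return_volume == 0) return(q)
  if (return_volume < 0) stop("return_volume must be >= 0")
  zero <- abs(q$value) < 1e-12
  if (!any(zero)) stop("no zero-flow window to place the pump return in")
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  zi <- which(r$values)
  best <- zi[which.max(r$lengths[zi])]
  i0 <- starts[best]; i1 <- ends[best]
  if (i1 - i0 < 10) stop("zero-flow window too short for a pump-return lobe")
  # keep one guard sample at each end so positive-phase samples are untouched
  i0 <- i0 + 1; i1 <- i1 - 1
  dur <- (i1 - i0) * trace_dt(q)
  amp <- return_volume / (dur * 2 / pi)  # half-sine integral = amp * dur * 2/pi
  idx <- i0:i1
  lobe <- -amp * sin(pi * (idx - i0) / (i1 - i0))
  v <- q$value
  v[idx] <- v[idx] + lobe
  time_trace(q$time, v, q$units)
}
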