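#' Segment a trace into cardiac cycles and average them
#'
#' Cuts consecutive non-overlapping windows of length `cycle_time` from
#' `start_index` onwards (the point from which the signal is considered
#' periodic); a trailing partial window is discarded. Returns the per-cycle
#' traces on a common cycle-time grid together with the pointwise mean and
#' standard-deviation traces. Averaging across cycles is the only smoothing
#' the pipeline applies.
#'
#' @param trace a `time_trace`
#' @param cycle_time cycle duration T in s
#' @param start_index 1-based sample index where segmentation starts; see
#'   [detect_periodic_start()] for an optional automatic choice
#' @return a `cycle_ensemble`: list with `cycle_time`, `cycles` (list of
#'   `time_trace`s on [0, T)), `mean_trace`, `sd_trace`, `units`
#' @export
segment_cycles <- function(trace, cycle_time, start_index = 1L) {
  dt <- trace_dt(trace)
  n1 <- round(cycle_time / dt)
  if (abs(n1 * dt - cycle_time) > 1e-6 * cycle_time)
    stop("cycle_time is not an integer number of samples")
  n_avail <- length(trace$value) - start_index + 1
  n_cyc <- floor(n_avail / n1)
  if (n_cyc < 2) stop("need at least 2 full cycles after start_index")
  tt <- (seq_len(n1) - 1) * dt
  vals <- matrix(trace$value[start_index - 1 + seq_len(n_cyc * n1)], n1, n_cyc)
  cycles <- lapply(seq_len(n_cyc), function(i) time_trace(tt, vals[, i], trace$units))
  mean_v <- rowMeans(vals)
  sd_v <- apply(vals, 1, stats::sd)
  structure(list(cycle_time = cycle_time, cycles = cycles,
                 mean_trace = time_trace(tt, mean_v, trace$units),
                 sd_trace = time_trace(tt, sd_v, trace$units),
                 units = trace$units),
            class = "cycle_ensemble")
}

#' @export
print.cycle_ensemble <- function(x, ...) {
  cat(sprintf("<cycle_ensemble> %d cycles of T = %g s [%s]\n",
              length(x$cycles), x$cycle_time, x$units))
  invisible(x)
}

#' Automatic start-of-periodicity detector
#'
#' The bench protocol discarded the start-up transient by eye; this optional
#' detector returns the first cycle index from which the cycle-to-cycle RMS
#' difference stays below 5% of the signal range.
#'
#' @param trace a `time_trace`
#' @param cycle_time cycle duration, s
#' @param rel_tol relative RMS tolerance (default 0.05)
#' @return 1-based sample index suitable for `start_index`
#' @export
detect_periodic_start <- function(trace, cycle_time, rel_tol = 0.05) {
  dt <- trace_dt(trace)
  n1 <- round(cycle_time / dt)
  n_cyc <- floor(length(trace$value) / n1)
  if (n_cyc < 2) stop("trace shorter than two cycles")
  rng <- diff(range(trace$value))
  for (i in seq_len(n_cyc - 1)) {
    a <- trace$value[(i - 1) * n1 + seq_len(n1)]
    b <- trace$value[i * n1 + seq_len(n1)]
    if (sqrt(mean((a - b)^2)) < rel_tol * rng) return((i - 1) * n1 + 1L)
  }
  stop("signal never becomes periodic at the requested tolerance")
}

#' Transvalvular pressure difference
#'
#' dp(t) = pLV(t) - pao(t). Both traces must share the same sampling grid;
#' no silent resampling is performed.
#'
#' @param p_lv,p_ao `time_trace`s in mmHg on a common grid
#' @return a `time_trace` of the difference, mmHg
#' @export
pressure_difference <- function(p_lv, p_ao) {
  if (length(p_lv$time) != length(p_ao$time) ||
      max(abs(p_lv$time - p_ao$time)) > 1e-9)
    stop("pressure traces are not on a common time grid")
  time_trace(p_lv$time, p_lv$value - p_ao$value, p_lv$units)
}

#' Periodically extend a one-cycle trace
#'
#' Repeats a cycle-averaged template to span `n_cycles` cardiac cycles, as
#' done to build the six-cycle boundary-condition signal for the simulations.
#'
#' @param mean_trace a `time_trace` covering exactly one cycle
#' @param n_cycles number of repetitions (default 6)
#' @return a `time_trace` of length `n_cycles * T`
#' @export
periodic_extend <- function(mean_trace, n_cycles = 6) {
  n1 <- length(mean_trace$value)
  dt <- trace_dt(mean_trace)
  n <- n1 * n_cycles
  time_trace((seq_len(n) - 1) * dt, rep(mean_trace$value, n_cycles),
             mean_trace$units)
}

# first sub-sample upward zero crossing of v (linear interpolation; an exact
# zero sample counts as a crossing)
first_up_crossing <- function(tt, v) {
  for (i in seq(2L, length(v))) {
    if (v[i - 1] <= 0 && v[i] > 0) {
      if (v[i - 1] == 0) return(tt[i - 1])
      return(tt[i - 1] + (0 - v[i - 1]) / (v[i] - v[i - 1]) * (tt[i] - tt[i - 1]))
    }
  }
  NA_real_
}

# first time v drops strictly below zero after t_after (linear interpolation
# of the 0-crossing; a preceding exact-zero sample dates the crossing there)
first_down_crossing <- function(tt, v, t_after) {
  for (i in seq(2L, length(v))) {
    if (tt[i] <= t_after) next
    if (v[i] < 0 && v[i - 1] >= 0) {
      if (v[i - 1] == 0) return(tt[i - 1])
      return(tt[i - 1] + v[i - 1] / (v[i - 1] - v[i]) * (tt[i] - tt[i - 1]))
    }
  }
  NA_real_
}

#' Ejection window of one cycle
#'
#' The ejection period starts at the crossing where pLV rises above pao and
#' ends at the first subsequent instant where the flow drops below zero.
#' If the flow never goes negative within the trace (possible in synthetic
#' data without a pump-return lobe), the end falls back to the downward
#' zero-crossing of the pressure difference. Crossing times are located by
#' linear interpolation between samples.
#'
#' @param q flow `time_trace` (mL/s)
#' @param p_lv,p_ao pressure `time_trace`s (mmHg) on the same grid as `q`
#' @return `c(t_start, t_end)` in s
#' @export
ejection_window <- function(q, p_lv, p_ao) {
  dp <- pressure_difference(p_lv, p_ao)
  tt <- dp$time
  t_start <- if (dp$value[1] > 0) tt[1] else first_up_crossing(tt, dp$value)
  if (is.na(t_start)) stop("no pLV > pao crossing found in the trace")
  t_end <- first_down_crossing(tt, q$value, t_start)
  if (is.na(t_end))  # fallback: flow never negative
    t_end <- first_down_crossing(tt, dp$value, t_start)
  if (is.na(t_end)) stop("no end of ejection found (neither Q < 0 nor dp < 0)")
  c(t_start = t_start, t_end = t_end)
}

#' Mean transvalvular flow over the ejection window
#'
#' Trapezoidal integral of the flow over the window divided by the window
#' duration.
#'
#' @param q flow `time_trace` (mL/s)
#' @param window `c(t_start, t_end)` in s
#' @return Qmean in mL/s
#' @export
q_mean <- function(q, window) {
  if (diff(window) <= 0) stop("zero-length ejection window")
  trace_integral(q, window[1], window[2]) / (window[2] - window[1])
}

#' Mean transvalvular pressure drop
#'
#' Mean of dp(t) over the contiguous region where dp > 0 in each cycle,
#' averaged over cycles. For a one-cycle trace this is the mean over its
#' positive phase; a negative diastolic plateau does not contribute.
#'
#' @param dp pressure-difference `time_trace` (mmHg), one or more cycles
#' @param cycle_time optional cycle duration; when given, the trace is split
#'   into cycles and per-cycle means are averaged
#' @return mean positive-phase pressure drop, mmHg
#' @export
dp_mean <- function(dp, cycle_time = NULL) {
  one <- function(v, tt) {
    pos <- v > 0
    if (!any(pos)) stop("dp <= 0 everywhere: no positive phase")
    # contiguous positive region: the run containing the maximum
    r <- rle(pos)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    runs <- which(r$values)
    imax <- which.max(v)
    run <- runs[starts[runs] <= imax & ends[runs] >= imax]
    i0 <- starts[run]; i1 <- ends[run]
    # extend to the sub-sample zero crossings (linear interpolation) so the
    # window is the true dp > 0 interval, not just the positive samples
    ts <- tt[i0:i1]; vs <- v[i0:i1]
    if (i0 > 1) {
      tc <- tt[i0 - 1] + (0 - v[i0 - 1]) / (v[i0] - v[i0 - 1]) * (tt[i0] - tt[i0 - 1])
      ts <- c(tc, ts); vs <- c(0, vs)
    }
    if (i1 < length(v)) {
      tc <- tt[i1] + (v[i1] - 0) / (v[i1] - v[i1 + 1]) * (tt[i1 + 1] - tt[i1])
      ts <- c(ts, tc); vs <- c(vs, 0)
    }
    # trapezoidal time-weighted mean over the positive interval
    sum(diff(ts) * (utils::head(vs, -1) + utils::tail(vs, -1)) / 2) /
      (ts[length(ts)] - ts[1])
  }
  if (is.null(cycle_time)) return(one(dp$value, dp$time))
  ens <- segment_cycles(dp, cycle_time)
  mean(vapply(ens$cycles, function(cy) one(cy$value, cy$time), numeric(1)))
}

#' Stroke volume over the ejection window
#'
#' Trapezoidal integral of the flow over the ejection window; equals
#' `q_mean(q, window) * diff(window)` by construction.
#'
#' @inheritParams q_mean
#' @return stroke volume in mL
#' @export
stroke_volume <- function(q, window) {
  trace_integral(q, window[1], window[2])
}

#' Mean and standard deviation of a per-cycle statistic
#'
#' @param values numeric vector, one value per cycle
#' @return `c(mean, sd)` (sample standard deviation)
#' @export
inter_cycle_stats <- function(values) {
  c(mean = mean(values), sd = stats::sd(values))
}

#' Measurement-uncertainty bounds
#'
#' Symmetric fractional uncertainty band around a measured value, defaulting
#' to the 10% accuracy of the ultrasonic flow probe.
#'
#' @param value measured value
#' @param frac fractional uncertainty (default 0.10)
#' @return `c(lo, hi)`
#' @export
uncertainty_bounds <- function(value, frac = 0.10) {
  c(lo = value * (1 - frac), hi = value * (1 + frac))
}

#' Haemodynamic summary of one experiment
#'
#' Convenience wrapper: segments the flow and pressure traces into cycles,
#' finds the per-cycle ejection window, and reports cycle statistics of the
#' mean transvalvular flow, pressure drop and stroke volume.
#'
#' @param q flow trace (mL/s), multiple cycles
#' @param p_lv,p_ao pressure traces (mmHg) on the same grid
#' @param cycle_time cycle duration, s
#' @param start_index first sample of the periodic portion
#' @param uncertainty_frac fractional measurement uncertainty for the bounds
#' @return a `hemo_summary` list: `q_mean`, `q_mean_sd`, `dp_mean`,
#'   `stroke_volume`, `ejection_window`, `q_bounds`, `uncertainty_frac`
#' @export
hemo_summary <- function(q, p_lv, p_ao, cycle_time, start_index = 1L,
                         uncertainty_frac = 0.10) {
  ens_q  <- segment_cycles(q, cycle_time, start_index)
  ens_lv <- segment_cycles(p_lv, cycle_time, start_index)
  ens_ao <- segment_cycles(p_ao, cycle_time, start_index)
  n <- length(ens_q$cycles)
  qm <- dpm <- sv <- numeric(n)
  win <- NULL
  for (i in seq_len(n)) {
    win <- ejection_window(ens_q$cycles[[i]], ens_lv$cycles[[i]], ens_ao$cycles[[i]])
    qm[i] <- q_mean(ens_q$cycles[[i]], win)
    dpc <- pressure_difference(ens_lv$cycles[[i]], ens_ao$cycles[[i]])
    dpm[i] <- dp_mean(dpc)
    sv[i] <- stroke_volume(ens_q$cycles[[i]], win)
  }
  qs <- inter_cycle_stats(qm)
  structure(list(
    q_mean = qs[["mean"]], q_mean_sd = qs[["sd"]],
    dp_mean = mean(dpm), stroke_volume = mean(sv),
    ejection_window = win, q_bounds = uncertainty_bounds(qs[["mean"]], uncertainty_frac),
    uncertainty_frac = uncertainty_frac, n_cycles = n
  ), class = "hemo_summary")
}

#' @export
print.hemo_summary <- function(x, ...) {
  cat(sprintf(
    "<hemo_summary> Qmean %.1f +/- %.1f mL/s, dpmean %.1f mmHg, SV %.1f mL (%d cycles)\n",
    x$q_mean, x$q_mean_sd, x$dp_mean, x$stroke_volume, x$n_cycles))
  invisible(x)
}
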