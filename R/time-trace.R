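#' Uniformly sampled scalar signal
#'
#' A `time_trace` is the basic signal container of the package: a uniformly
#' sampled scalar time series with a unit label. Time is always in seconds.
#'
#' @param time numeric vector of sample times (s), uniformly spaced, increasing
#' @param value numeric vector, same length as `time`
#' @param units character unit label for `value` (e.g. "mmHg", "mL/s")
#' @return an object of class `time_trace` with fields `time`, `value`, `units`
#' @export
time_trace <- function(time, value, units = "") {
  stopifnot(is.numeric(time), is.numeric(value), length(time) == length(value),
            length(time) >= 2)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-8 * mean(dt))
    stop("time_trace requires uniform sampling")
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 units = units), class = "time_trace")
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf("<time_trace> %d samples over %.4g s [%s], dt = %.4g s\n",
              length(x$time), diff(range(x$time)), x$units,
              x$time[2] - x$time[1]))
  invisible(x)
}

#' @export
length.time_trace <- function(x) length(x$time)

#' Sampling interval of a trace
#' @param x a `time_trace`
#' @return scalar dt in seconds
#' @export
trace_dt <- function(x) x$time[2] - x$time[1]

#' Trapezoidal integral of a trace
#'
#' @param x a `time_trace`
#' @param t0,t1 optional window limits (s); defaults to the full trace.
#'   Window endpoints are snapped by linear interpolation so partial end
#'   intervals are integrated exactly for piecewise-linear signals.
#' @return the integral of `value` over time (value-units times seconds)
#' @export
trace_integral <- function(x, t0 = NULL, t1 = NULL) {
  tt <- x$time; vv <- x$value
  if (is.null(t0)) t0 <- tt[1]
  if (is.null(t1)) t1 <- tt[length(tt)]
  if (t1 <= t0) stop("empty integration window")
  if (t0 < tt[1] - 1e-12 || t1 > tt[length(tt)] + 1e-12)
    stop("integration window outside trace")
  t0 <- max(t0, tt[1]); t1 <- min(t1, tt[length(tt)])
  inside <- tt > t0 & tt < t1
  ts <- c(t0, tt[inside], t1)
  vs <- c(stats::approx(tt, vv, xout = t0)$y, vv[inside],
          stats::approx(tt, vv, xout = t1)$y)
  sum(diff(ts) * (utils::head(vs, -1) + utils::tail(vs, -1)) / 2)
}

#' Write / read a trace as a two-column CSV
#'
#' Plain-text interchange format: columns `time_s` and `value`, plus a JSON
#' sidecar (`<path>.json`) carrying the unit label and any cycle metadata.
#'
#' @param x a `time_trace`
#' @param path CSV path
#' @param meta optional named list of extra metadata for the sidecar
#' @return `path`, invisibly
#' @export
write_trace_csv <- function(x, path, meta = list()) {
  utils::write.csv(data.frame(time_s = x$time, value = x$value), path,
                   row.names = FALSE)
  side <- c(list(units = x$units), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  units <- ""
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$units)) units <- meta$units
  }
  time_trace(df$time_s, df$value, units = units)
}
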