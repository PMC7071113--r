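#' Uniformly sampled signal channel
#'
#' The atom of all processing in \pkg{macx}: a named, uniformly sampled
#' sequence of finite real values with an explicit sampling rate.
#'
#' @param samples numeric vector of finite sample values. `NA`/`NaN`/`Inf`
#'   are rejected: silently imputing missing samples would corrupt every
#'   downstream correlation estimate, so ingestion must fail loudly instead.
#' @param rate sampling rate in Hz, a single positive number.
#' @param name channel label, e.g. `"ecg"` or `"left_Z"`.
#' @param t0 start-time offset in seconds (default 0).
#'
#' @return An object of class `macx_ts`: a numeric vector with attributes
#'   `rate`, `name`, `t0`.
#' @examples
#' ts <- timeseries(sin(2 * pi * (0:199) / 200), rate = 200, name = "demo")
#' duration(ts)
#' @export
timeseries <- function(samples, rate, name = "signal", t0 = 0) {
  if (!is.numeric(samples)) {
    stop("samples must be numeric, got ", class(samples)[1L])
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    bad <- which(!is.finite(samples))[1L]
    stop("non-finite sample at position ", bad, " in channel '", name,
         "' (NaN/Inf are rejected at ingestion, not imputed)")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number (Hz)")
  }
  structure(as.numeric(samples),
            rate = as.numeric(rate), name = as.character(name),
            t0 = as.numeric(t0), class = "macx_ts")
}

#' @export
print.macx_ts <- function(x, ...) {
  cat(sprintf("<macx_ts '%s': %d samples @ %g Hz (%.3f s)>\n",
              ts_name(x), length(x), ts_rate(x), duration(x)))
  invisible(x)
}

#' Sampling rate of a channel in Hz
#' @param ts a `macx_ts`.
#' @return a single number.
#' @export
ts_rate <- function(ts) attr(ts, "rate")

#' Channel label
#' @inheritParams ts_rate
#' @return a single string.
#' @export
ts_name <- function(ts) attr(ts, "name")

#' Duration in seconds (`length / rate`)
#' @inheritParams ts_rate
#' @return a single number.
#' @export
duration <- function(ts) length(ts) / ts_rate(ts)

#' Sample times in seconds
#' @inheritParams ts_rate
#' @return numeric vector `t0 + (0:(n-1))/rate`.
#' @export
ts_times <- function(ts) attr(ts, "t0") + (seq_along(ts) - 1) / ts_rate(ts)

# internal: numeric payload without attributes
ts_values <- function(ts) as.numeric(unclass(ts))

# internal: rebuild a series with new samples, keeping metadata
ts_replace <- function(ts, samples, rate = ts_rate(ts), name = ts_name(ts),
                       t0 = attr(ts, "t0")) {
  timeseries(samples, rate = rate, name = name, t0 = t0)
}

# internal: coerce numeric or macx_ts to plain numeric
as_samples <- function(x) {
  if (inherits(x, "macx_ts")) ts_values(x) else as.numeric(x)
}

#' Six-axis inertial sensor record
#'
#' Bundles the three accelerometer axes (X, Y, Z) and three gyroscope axes
#' (U, V, W — angular rate about x, y, z) of one body-worn inertial module.
#' All six channels must share one sampling rate and length.
#'
#' @param sensor_id placement label, e.g. `"left"`, `"middle"`, `"right"`.
#' @param axes named list of six `macx_ts`, names exactly X, Y, Z, U, V, W.
#' @return An object of class `macx_sensor`.
#' @export
inertial_sensor <- function(sensor_id, axes) {
  need <- AXIS_NAMES
  missing <- setdiff(need, names(axes))
  if (length(missing) > 0) {
    stop("sensor '", sensor_id, "' is missing axis channel(s): ",
         paste(missing, collapse = ", "))
  }
  axes <- axes[need]
  rates <- vapply(axes, ts_rate, numeric(1))
  lens <- vapply(axes, length, integer(1))
  if (length(unique(rates)) != 1L || length(unique(lens)) != 1L) {
    stop("sensor '", sensor_id,
         "': all six axis channels must share one rate and one length")
  }
  structure(list(sensor_id = as.character(sensor_id), axes = axes),
            class = "macx_sensor")
}

AXIS_NAMES <- c("X", "Y", "Z", "U", "V", "W")
CANDIDATE_CHANNELS <- c(AXIS_NAMES, "R")

#' @export
print.macx_sensor <- function(x, ...) {
  cat(sprintf("<macx_sensor '%s': 6 axes, %d samples @ %g Hz>\n",
              x$sensor_id, length(x$axes$X), ts_rate(x$axes$X)))
  invisible(x)
}

#' Multi-channel recording: one ECG plus M inertial sensors
#'
#' @param ecg `macx_ts`: the contaminated single-lead ECG, the main input
#'   of the canceller (clean cardiac signal plus motion artifact).
#' @param sensors list of `macx_sensor` objects, M >= 1.
#' @param meta free-form named list of provenance (file paths, applied
#'   alignment lags, column mapping, ...).
#' @return An object of class `macx_recording`.
#' @export
recording <- function(ecg, sensors, meta = list()) {
  stopifnot(inherits(ecg, "macx_ts"))
  if (length(sensors) < 1L) stop("a recording needs at least one sensor")
  for (s in sensors) stopifnot(inherits(s, "macx_sensor"))
  ids <- vapply(sensors, function(s) s$sensor_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sensor_id in recording")
  names(sensors) <- ids
  structure(list(ecg = ecg, sensors = sensors, meta = meta),
            class = "macx_recording")
}

#' @export
print.macx_recording <- function(x, ...) {
  cat(sprintf("<macx_recording: ecg %d samples @ %g Hz, %d sensor(s): %s>\n",
              length(x$ecg), ts_rate(x$ecg), length(x$sensors),
              paste(names(x$sensors), collapse = ", ")))
  invisible(x)
}

# internal: all channels of a recording as a named list of macx_ts
recording_channels <- function(rec) {
  out <- list(ecg = rec$ecg)
  for (s in rec$sensors) {
    for (ax in AXIS_NAMES) {
      out[[paste0(s$sensor_id, "_", ax)]] <- s$axes[[ax]]
    }
  }
  out
}
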