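#' Resample a channel to a new rate by cubic-spline interpolation
#'
#' Fits a cubic spline through the original samples and evaluates it on the
#' uniform grid of the target rate, spanning the same time interval (new
#' length `floor(duration * target_rate)`). Evaluation times are clamped to
#' the last original sample time, so the spline is never extrapolated.
#'
#' When decimating (`target_rate < rate(ts)`), an anti-alias low-pass is
#' applied first: an order-8 Butterworth at 0.45 x target rate, run
#' forward and backward (zero phase). The channel mean is removed before
#' filtering and restored afterwards, so constant signals pass through
#' exactly.
#'
#' @param ts a [timeseries()] with at least 4 samples.
#' @param target_rate new sampling rate in Hz (> 0).
#' @param antialias apply the low-pass before decimating? Default `TRUE`;
#'   ignored when upsampling.
#' @return A [timeseries()] at `target_rate`.
#' @export
resample_cubic <- function(ts, target_rate, antialias = TRUE) {
  stopifnot(inherits(ts, "macx_ts"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0) {
    stop("target_rate must be a single positive number (Hz)")
  }
  n <- length(ts)
  if (n < 4L) stop("cubic spline interpolation needs at least 4 samples, got ", n)
  r <- ts_rate(ts)
  x <- ts_values(ts)
  if (antialias && target_rate < r) {
    mu <- mean(x)
    bf <- signal::butter(8, 0.45 * target_rate / (r / 2), type = "low")
    x <- signal::filtfilt(bf, x - mu) + mu
  }
  tt <- (seq_len(n) - 1) / r
  m <- floor(n / r * target_rate)
  t_new <- pmin((seq_len(m) - 1) / target_rate, tt[n])
  f <- stats::splinefun(tt, x, method = "fmm")
  timeseries(f(t_new), rate = target_rate, name = ts_name(ts),
             t0 = attr(ts, "t0"))
}

#' Resample every channel of a recording to one common rate
#'
#' @param rec a [recording()].
#' @param target_rate common rate in Hz (default 200).
#' @param antialias passed to [resample_cubic()].
#' @return A [recording()] whose channels all share `target_rate`.
#' @export
resample_recording <- function(rec, target_rate = 200, antialias = TRUE) {
  stopifnot(inherits(rec, "macx_recording"))
  ecg <- resample_cubic(rec$ecg, target_rate, antialias)
  sensors <- lapply(rec$sensors, function(s) {
    axes <- lapply(s$axes, resample_cubic, target_rate = target_rate,
                   antialias = antialias)
    inertial_sensor(s$sensor_id, axes)
  })
  meta <- rec$meta
  meta$target_rate_hz <- target_rate
  recording(ecg, sensors, meta)
}

#' Estimate the integer-sample lag of one channel relative to another
#'
#' Searches `lag` in `[-max_lag, max_lag]` for the value maximizing the
#' absolute cross-correlation `sum_t a[t] * b[t + lag]` of the mean-removed
#' signals; `lag > 0` means `b` lags (is delayed relative to) `a`.
#'
#' @param a,b numeric vectors or [timeseries()] at the same rate.
#' @param max_lag search half-window in samples.
#' @return integer lag; 0 with a warning if either input has zero variance.
#' @export
estimate_lag <- function(a, b, max_lag) {
  a <- as_samples(a); b <- as_samples(b)
  n <- min(length(a), length(b))
  max_lag <- as.integer(max_lag)
  if (max_lag >= n) {
    stop("lag search window (", max_lag, " samples) is not smaller than ",
         "the signal (", n, " samples)")
  }
  a <- a[seq_len(n)] - mean(a[seq_len(n)])
  b <- b[seq_len(n)] - mean(b[seq_len(n)])
  if (sum(a^2) == 0 || sum(b^2) == 0) {
    warning("zero-variance channel in lag estimation; falling back to lag 0")
    return(0L)
  }
  lags <- seq.int(-max_lag, max_lag)
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(a[seq_len(n - k)] * b[seq_len(n - k) + k])
    else        sum(a[seq_len(n + k) - k] * b[seq_len(n + k)])
  }, numeric(1))
  lags[which.max(abs(cc))]
}

#' Time-align inertial sensors to the ECG
#'
#' Shifts each sensor's six channels by one integer-sample lag and truncates
#' all channels (ECG included) to the common overlapping span. With
#' `method = "xcorr"` the lag is the one maximizing the absolute
#' cross-correlation between the sensor's acceleration magnitude
#' (see [acceleration_magnitude()]) and the ECG, searched within
#' `+/- window_s` seconds. With `method = "manual"` the per-sensor lags (in
#' seconds) are taken from `manual_lags` (missing entries default to 0).
#' Sub-sample delays are deliberately not corrected: the adaptive filter's
#' tap line absorbs them.
#'
#' @param rec a [recording()] whose channels share one rate.
#' @param method `"xcorr"` (default) or `"manual"`.
#' @param manual_lags named numeric vector/list of lags in seconds per
#'   sensor id (positive = sensor is delayed relative to the ECG).
#' @param window_s cross-correlation search half-window in seconds
#'   (default 2).
#' @return The aligned [recording()]; applied lags (samples and seconds)
#'   are recorded in `$meta$applied_lags`.
#' @export
align_recording <- function(rec, method = c("xcorr", "manual"),
                            manual_lags = NULL, window_s = 2) {
  stopifnot(inherits(rec, "macx_recording"))
  method <- match.arg(method)
  rate <- ts_rate(rec$ecg)
  rates <- vapply(recording_channels(rec), ts_rate, numeric(1))
  if (any(rates != rate)) {
    stop("align_recording requires all channels at one common rate; ",
         "call resample_recording() first")
  }
  lags <- vapply(rec$sensors, function(s) {
    if (method == "manual") {
      lag_s <- if (!is.null(manual_lags) && !is.null(manual_lags[[s$sensor_id]]))
        as.numeric(manual_lags[[s$sensor_id]]) else 0
      as.integer(round(lag_s * rate))
    } else {
      mag <- acceleration_magnitude(s$axes$X, s$axes$Y, s$axes$Z)
      estimate_lag(rec$ecg, mag, max_lag = as.integer(round(window_s * rate)))
    }
  }, integer(1))

  n_ecg <- length(rec$ecg)
  n_sen <- vapply(rec$sensors, function(s) length(s$axes$X), integer(1))
  t_start <- max(1L, 1L - min(lags))
  t_end <- min(n_ecg, min(n_sen - lags))
  if (t_end - t_start < 1L) stop("no overlapping span after alignment")

  ecg <- ts_replace(rec$ecg, ts_values(rec$ecg)[t_start:t_end])
  sensors <- mapply(function(s, lag) {
    idx <- (t_start + lag):(t_end + lag)
    axes <- lapply(s$axes, function(ch) ts_replace(ch, ts_values(ch)[idx]))
    inertial_sensor(s$sensor_id, axes)
  }, rec$sensors, lags, SIMPLIFY = FALSE)

  meta <- rec$meta
  meta$applied_lags <- list(samples = stats::setNames(as.list(lags),
                                                      names(rec$sensors)),
                            seconds = stats::setNames(as.list(lags / rate),
                                                      names(rec$sensors)),
                            method = method)
  meta$ecg_span <- c(t_start, t_end)  # indices kept from the input ECG
  recording(ecg, sensors, meta)
}
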