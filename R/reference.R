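#' Acceleration vector magnitude
#'
#' Pointwise Euclidean norm of the three accelerometer axes,
#' `R = sqrt(X^2 + Y^2 + Z^2)` — the orientation-free summary of sensor
#' motion, used both as a seventh reference candidate and as the channel
#' driving cross-correlation alignment.
#'
#' @param x,y,z the three accelerometer axis channels ([timeseries()]),
#'   equal length and rate.
#' @return A [timeseries()] named `"R"`.
#' @export
acceleration_magnitude <- function(x, y, z) {
  for (ch in list(x, y, z)) stopifnot(inherits(ch, "macx_ts"))
  if (length(unique(c(length(x), length(y), length(z)))) != 1L) {
    stop("axis length mismatch in acceleration_magnitude")
  }
  if (length(unique(c(ts_rate(x), ts_rate(y), ts_rate(z)))) != 1L) {
    stop("axis rate mismatch in acceleration_magnitude")
  }
  timeseries(sqrt(ts_values(x)^2 + ts_values(y)^2 + ts_values(z)^2),
             rate = ts_rate(x), name = "R", t0 = attr(x, "t0"))
}

#' Pearson correlation between two equal-length channels
#'
#' The product-moment correlation used throughout the pipeline to score
#' reference candidates against the contaminated ECG. Returns `NA` (the
#' "undefined" sentinel) when either input has zero variance, where the
#' denominator of the coefficient vanishes.
#'
#' @param d,x numeric vectors or [timeseries()] of equal length >= 2.
#' @return A number in `[-1, 1]`, or `NA` for a zero-variance input.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
#' @export
pearson_cor <- function(d, x) {
  d <- as_samples(d); x <- as_samples(x)
  if (length(d) != length(x)) {
    stop("length mismatch in pearson_cor: ", length(d), " vs ", length(x))
  }
  if (length(d) < 2L) stop("pearson_cor needs at least 2 samples")
  if (stats::sd(d) == 0 || stats::sd(x) == 0) return(NA_real_)
  stats::cor(d, x)
}

#' Score one sensor's candidate channels against the ECG
#'
#' Computes the Pearson correlation between the main input `d` and each of
#' the sensor's seven candidate channels — the six axes X, Y, Z, U, V, W
#' and the derived acceleration magnitude R — and picks the candidate with
#' the largest absolute correlation. Ties break on the fixed channel order
#' X, Y, Z, U, V, W, R; zero-variance channels score `NA` and are excluded
#' (with a warning).
#'
#' @param d the main input ECG ([timeseries()]), aligned and resampled to
#'   the sensor's rate and length.
#' @param sensor a [inertial_sensor()].
#' @return A list: `table` (data.frame sensor_id/channel/rho),
#'   `best_channel`, `best_rho`, and `nu` (the winning channel, unchanged).
#' @export
score_sensor <- function(d, sensor) {
  stopifnot(inherits(d, "macx_ts"), inherits(sensor, "macx_sensor"))
  cand <- sensor$axes
  cand$R <- acceleration_magnitude(sensor$axes$X, sensor$axes$Y,
                                   sensor$axes$Z)
  rho <- vapply(CANDIDATE_CHANNELS,
                function(ch) pearson_cor(d, cand[[ch]]), numeric(1))
  if (anyNA(rho)) {
    warning("sensor '", sensor$sensor_id, "': zero-variance channel(s) ",
            paste(CANDIDATE_CHANNELS[is.na(rho)], collapse = ", "),
            " excluded from selection")
  }
  if (all(is.na(rho))) {
    stop("no usable channel on sensor '", sensor$sensor_id,
         "': all candidates have zero variance")
  }
  score <- abs(rho)
  score[is.na(score)] <- -Inf
  best <- which.max(score)
  list(table = data.frame(sensor_id = sensor$sensor_id,
                          channel = CANDIDATE_CHANNELS,
                          rho = unname(rho),
                          stringsAsFactors = FALSE),
       best_channel = CANDIDATE_CHANNELS[best],
       best_rho = unname(rho[best]),
       nu = cand[[best]])
}

#' Select the single best reference channel across all sensors
#'
#' Applies [score_sensor()] to each of the M sensors and takes the winner
#' with the largest absolute correlation across sensors (ties break on the
#' lowest sensor index, then the fixed channel order). The winning channel
#' is returned unmodified as `nu`, the raw reference handed to wavelet
#' conditioning. Because the winner is a maximum over a growing candidate
#' set, its absolute correlation can only increase as sensors are added.
#'
#' @param d the main input ECG ([timeseries()]).
#' @param sensors list of [inertial_sensor()] (M >= 1), aligned to `d`.
#' @return An object of class `macx_selection`: list with `winner_sensor`,
#'   `winner_channel`, `winner_rho`, `table` (full 7 x M correlation
#'   table), and `nu`.
#' @export
select_reference <- function(d, sensors) {
  if (inherits(sensors, "macx_sensor")) sensors <- list(sensors)
  if (inherits(sensors, "macx_recording")) {
    d <- sensors$ecg
    sensors <- sensors$sensors
  }
  if (length(sensors) < 1L) stop("select_reference needs at least one sensor")
  scored <- lapply(sensors, function(s) score_sensor(d, s))
  table <- do.call(rbind, lapply(scored, `[[`, "table"))
  best_rhos <- vapply(scored, `[[`, numeric(1), "best_rho")
  win <- which.max(abs(best_rhos))  # which.max takes the first on ties
  sel <- scored[[win]]
  structure(list(winner_sensor = sensors[[win]]$sensor_id,
                 winner_channel = sel$best_channel,
                 winner_rho = sel$best_rho,
                 table = table,
                 nu = sel$nu),
            class = "macx_selection")
}

#' @export
print.macx_selection <- function(x, ...) {
  cat(sprintf("<macx_selection: winner %s/%s, rho = %.4f (%d sensors)>\n",
              x$winner_sensor, x$winner_channel, x$winner_rho,
              length(unique(x$table$sensor_id))))
  invisible(x)
}
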