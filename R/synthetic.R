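#' Mixing weights that plant a target correlation
#'
#' For a channel built as `w * source + noise` with unit-variance,
#' independent `source` and `noise`, the correlation with `source` is
#' `w / sqrt(w^2 + 1)`; inverting gives `w = rho / sqrt(1 - rho^2)`.
#'
#' @param rho target correlation in (-1, 1).
#' @return Named numeric vector `c(hidden, decoy, noise)` of mixing
#'   weights.
#' @export
mix_weights_for_rho <- function(rho) {
  stopifnot(abs(rho) < 1)
  c(hidden = rho / sqrt(1 - rho^2), decoy = 0, noise = 1)
}

# default per-axis target correlations to the hidden motion source;
# "middle"/Z is the planted winner, emulating the electrode-adjacent module
DEFAULT_RHO_TABLE <- list(
  left   = c(X = 0.10, Y = 0.20, Z = 0.30, U = 0.05, V = 0.50, W = 0.15),
  middle = c(X = 0.20, Y = 0.30, Z = 0.90, U = 0.15, V = 0.10, W = 0.25),
  right  = c(X = 0.15, Y = 0.40, Z = 0.10, U = 0.20, V = 0.05, W = 0.30)
)

default_channel_mixing <- function(n_sensors = 3) {
  if (n_sensors == 3) {
    tab <- DEFAULT_RHO_TABLE
  } else {
    ids <- paste0("s", seq_len(n_sensors))
    tab <- rep(DEFAULT_RHO_TABLE, length.out = n_sensors)
    names(tab) <- ids
  }
  lapply(tab, function(axes) lapply(as.list(axes), mix_weights_for_rho))
}

DEFAULT_MORPHOLOGY <- list(
  P = c(amplitude = 0.12, width_s = 0.025, offset_s = -0.200),
  Q = c(amplitude = -0.12, width_s = 0.010, offset_s = -0.035),
  R = c(amplitude = 1.00, width_s = 0.012, offset_s = 0.000),
  S = c(amplitude = -0.20, width_s = 0.010, offset_s = 0.035),
  T = c(amplitude = 0.35, width_s = 0.045, offset_s = 0.250)
)

#' Synthetic-recording settings
#'
#' Defines the study conditions emulated by [synth_generate()]: a
#' quasi-periodic ECG built from per-beat Gaussian P-Q-R-S-T bumps, a
#' motion artifact obtained by FIR-filtering a hidden band-limited motion
#' source (0.5–5 Hz, the gross body-motion band), and M six-axis inertial
#' sensors whose channels are planted mixtures of the hidden source, an
#' artifact-irrelevant "decoy" vibration in a disjoint high band, and
#' white noise.
#'
#' @param rate sampling rate in Hz (default 200).
#' @param duration_s record length in seconds (default 60, the study's
#'   minimum per activity).
#' @param heart_rate_bpm mean heart rate (default 60).
#' @param beat_jitter_s s.d. of the Gaussian jitter on beat times
#'   (default 0.02).
#' @param morphology named list P/Q/R/S/T of
#'   `c(amplitude, width_s, offset_s)` Gaussian bump parameters.
#' @param artifact_gain artifact amplitude as a multiple of the clean
#'   ECG's standard deviation (default 1: artifact power equals cardiac
#'   power, so `MSE(d, s) / var(s)` is about 1).
#' @param artifact_fir FIR taps mapping the hidden motion source to the
#'   artifact (default `c(0.6, 0.3, 0.1)`, a short electrode-motion
#'   impulse response).
#' @param artifact_band_hz pass band of the hidden motion source
#'   (default `c(0.5, 5)`).
#' @param decoy_band_hz pass band of the artifact-irrelevant sensor
#'   vibration (default `c(20, 45)`, disjoint from the artifact band).
#' @param n_sensors number of inertial modules M (default 3:
#'   left / middle / right).
#' @param channel_mixing nested list `sensor -> axis -> c(hidden, decoy,
#'   noise)` mixing weights on the unit-variance components; defaults to a
#'   fixed table whose strongest planting (rho 0.9) is middle/Z. See
#'   [mix_weights_for_rho()].
#' @param sensor_lag_s named per-sensor delay in seconds applied to all
#'   six channels (default 0).
#' @param gravity_offset static acceleration added to every sensor's Z
#'   axis, in the same units as the motion mixtures (default 9.81, i.e.
#'   m/s^2 with unit-variance motion of about 0.1 g). Real accelerometers
#'   always carry this component; it is also what makes the acceleration
#'   magnitude informative for alignment, since |g + m| is approximately
#'   linear in the motion projected on gravity.
#' @param seed integer; mandatory, every random draw flows from it.
#' @return A list of class `macx_synthcfg`.
#' @export
synth_config <- function(rate = 200, duration_s = 60, heart_rate_bpm = 60,
                         beat_jitter_s = 0.02,
                         morphology = DEFAULT_MORPHOLOGY,
                         artifact_gain = 1,
                         artifact_fir = c(0.6, 0.3, 0.1),
                         artifact_band_hz = c(0.5, 5),
                         decoy_band_hz = c(20, 45),
                         n_sensors = 3, channel_mixing = NULL,
                         sensor_lag_s = NULL, gravity_offset = 9.81,
                         seed) {
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory: unseeded generation is not allowed")
  }
  stopifnot(rate > 0, duration_s > 0, heart_rate_bpm > 0,
            artifact_gain >= 0, n_sensors >= 1)
  morphology <- lapply(morphology, function(w) {
    w <- unlist(w)
    # YAML serialization drops vector names; accept canonical order
    if (is.null(names(w))) names(w) <- c("amplitude", "width_s", "offset_s")
    stats::setNames(as.numeric(w[c("amplitude", "width_s", "offset_s")]),
                    c("amplitude", "width_s", "offset_s"))
  })
  if (is.null(channel_mixing)) {
    channel_mixing <- default_channel_mixing(n_sensors)
  }
  channel_mixing <- lapply(channel_mixing, function(axes) {
    lapply(axes, function(w) {
      w <- unlist(w)
      if (is.null(names(w))) names(w) <- c("hidden", "decoy", "noise")
      w <- stats::setNames(as.numeric(w[c("hidden", "decoy", "noise")]),
                           c("hidden", "decoy", "noise"))
      if (anyNA(w)) stop("channel_mixing entries need hidden/decoy/noise")
      w
    })
  })
  structure(list(rate = rate, duration_s = duration_s,
                 heart_rate_bpm = heart_rate_bpm,
                 beat_jitter_s = beat_jitter_s, morphology = morphology,
                 artifact_gain = artifact_gain,
                 artifact_fir = as.numeric(artifact_fir),
                 artifact_band_hz = as.numeric(artifact_band_hz),
                 decoy_band_hz = as.numeric(decoy_band_hz),
                 n_sensors = as.integer(n_sensors),
                 channel_mixing = channel_mixing,
                 sensor_lag_s = sensor_lag_s,
                 gravity_offset = gravity_offset,
                 seed = as.integer(seed)),
            class = "macx_synthcfg")
}

# internal: deterministic sub-seed per generator component, < 2^31
macx_subseed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 7919 + k * 104729) %%
               2147483647)
}

# internal: unit-variance band-limited Gaussian noise
band_noise <- function(n, rate, band_hz, seed) {
  set.seed(seed)
  w <- stats::rnorm(n)
  bf <- signal::butter(4, band_hz / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, w)
  x / stats::sd(x)
}

# internal: clean ECG from Gaussian bumps; returns samples + fiducials
synth_clean_ecg <- function(cfg) {
  n <- round(cfg$duration_s * cfg$rate)
  period <- 60 / cfg$heart_rate_bpm
  k <- seq_len(floor(cfg$duration_s / period))
  set.seed(macx_subseed(cfg$seed, 1L))
  beat_t <- (k - 0.5) * period + stats::rnorm(length(k), 0, cfg$beat_jitter_s)
  tt <- (seq_len(n) - 1) / cfg$rate
  ecg <- numeric(n)
  span <- 0.45  # bump support per beat, seconds each side of the R wave
  for (bt in beat_t) {
    lo <- max(1L, floor((bt - span) * cfg$rate) + 1L)
    hi <- min(n, ceiling((bt + span) * cfg$rate) + 1L)
    if (lo > hi) next
    tw <- tt[lo:hi]
    for (wv in cfg$morphology) {
      ecg[lo:hi] <- ecg[lo:hi] + wv["amplitude"] *
        exp(-((tw - bt - wv["offset_s"])^2) / (2 * wv["width_s"]^2))
    }
  }
  fid <- round(beat_t * cfg$rate) + 1L
  fid <- fid[fid >= 1L & fid <= n]
  list(samples = ecg, fiducials = as.integer(fid))
}

#' Generate a synthetic recording with known ground truth
#'
#' Builds, deterministically from `cfg$seed`: the clean ECG `s(n)`; the
#' hidden motion source (band-limited noise); the artifact
#' `v(n) = gain * (h * hidden)`; the contaminated ECG
#' `d(n) = s(n) + v(n)` (sample-exact); and every sensor axis as a planted
#' mixture of the hidden source, the sensor's decoy vibration, and white
#' noise. Randomness is split into per-component sub-seeds (jitter, hidden
#' source, one per sensor decoy, one per axis noise), so changing one
#' component's settings does not perturb the others' draws.
#'
#' @param cfg a [synth_config()].
#' @return List with `recording` (a [recording()]) and `truth`: list of
#'   `clean_ecg`, `artifact`, `hidden_source` (all [timeseries()]),
#'   `beat_fiducials`, `true_winner` (`c(sensor, axis)` with the largest
#'   planted hidden weight), and `config`.
#' @export
synth_generate <- function(cfg) {
  stopifnot(inherits(cfg, "macx_synthcfg"))
  n <- round(cfg$duration_s * cfg$rate)
  ecg0 <- synth_clean_ecg(cfg)
  hidden <- band_noise(n, cfg$rate, cfg$artifact_band_hz,
                       macx_subseed(cfg$seed, 2L))
  art <- as.numeric(stats::filter(hidden, cfg$artifact_fir, method = "convolution",
                                  sides = 1))
  art[is.na(art)] <- 0
  if (cfg$artifact_gain > 0 && stats::sd(art) > 0) {
    art <- art / stats::sd(art) * cfg$artifact_gain * stats::sd(ecg0$samples)
  } else {
    art <- numeric(n)
  }
  d <- ecg0$samples + art

  sensors <- vector("list", length(cfg$channel_mixing))
  ids <- names(cfg$channel_mixing)
  for (si in seq_along(ids)) {
    sid <- ids[si]
    decoy <- band_noise(n, cfg$rate, cfg$decoy_band_hz,
                        macx_subseed(cfg$seed, 10L + si))
    axes <- list()
    for (ai in seq_along(AXIS_NAMES)) {
      ax <- AXIS_NAMES[ai]
      w <- cfg$channel_mixing[[sid]][[ax]]
      set.seed(macx_subseed(cfg$seed, 100L + 10L * si + ai))
      ch <- w["hidden"] * hidden + w["decoy"] * decoy +
        w["noise"] * stats::rnorm(n)
      lag_s <- if (!is.null(cfg$sensor_lag_s)) cfg$sensor_lag_s[[sid]] else NULL
      if (!is.null(lag_s) && lag_s != 0) {
        k <- as.integer(round(lag_s * cfg$rate))
        ch <- if (k > 0) c(numeric(k), ch[seq_len(n - k)])
              else c(ch[(1 - k):n], numeric(-k))
      }
      if (ax == "Z") ch <- ch + cfg$gravity_offset
      # gravity after the shift, so lag padding does not inject a step
      axes[[ax]] <- timeseries(ch, rate = cfg$rate,
                               name = paste0(sid, "_", ax))
    }
    sensors[[si]] <- inertial_sensor(sid, axes)
  }

  hidden_w <- unlist(lapply(cfg$channel_mixing, function(axes)
    vapply(axes, function(w) abs(w["hidden"]) / sqrt(sum(w^2)), numeric(1))))
  best <- which.max(hidden_w)
  winner <- strsplit(names(hidden_w)[best], ".", fixed = TRUE)[[1]]
  winner[2] <- sub("\\.hidden$", "", winner[2])

  rec <- recording(timeseries(d, cfg$rate, "ecg"), sensors,
                   meta = list(synthetic = TRUE, seed = cfg$seed))
  truth <- list(clean_ecg = timeseries(ecg0$samples, cfg$rate, "clean_ecg"),
                artifact = timeseries(art, cfg$rate, "artifact"),
                hidden_source = timeseries(hidden, cfg$rate, "hidden"),
                beat_fiducials = ecg0$fiducials,
                true_winner = c(sensor = winner[1], axis = winner[2]),
                config = cfg)
  list(recording = rec, truth = truth)
}

#' Generate the decoy scenario: diluted reference, recoverable by wavelets
#'
#' Same machinery as [synth_generate()], but the planted winner axis
#' additionally carries strong decoy vibration: its decoy weight is set so
#' the decoy component's power is `decoy_power_ratio` times the
#' artifact-correlated component's power. Because decoy and artifact
#' occupy disjoint octave bands, the raw channel's correlation with the
#' ECG is diluted, and wavelet band retention should recover it.
#'
#' @param cfg a [synth_config()].
#' @param decoy_power_ratio decoy-to-correlated power ratio on the winner
#'   axis (default 4).
#' @return As [synth_generate()]; `truth$decoy_power_ratio` records the
#'   planted ratio.
#' @export
synth_generate_decoy <- function(cfg, decoy_power_ratio = 4) {
  stopifnot(inherits(cfg, "macx_synthcfg"), decoy_power_ratio >= 0)
  if (max(cfg$artifact_band_hz) >= min(cfg$decoy_band_hz)) {
    stop("decoy band [", paste(cfg$decoy_band_hz, collapse = ", "),
         "] Hz must be disjoint from (above) the artifact band [",
         paste(cfg$artifact_band_hz, collapse = ", "), "] Hz")
  }
  hidden_w <- unlist(lapply(cfg$channel_mixing, function(axes)
    vapply(axes, function(w) abs(w["hidden"]), numeric(1))))
  best <- names(hidden_w)[which.max(hidden_w)]
  parts <- strsplit(sub("\\.hidden$", "", best), ".", fixed = TRUE)[[1]]
  w <- cfg$channel_mixing[[parts[1]]][[parts[2]]]
  w["decoy"] <- sqrt(decoy_power_ratio) * abs(w["hidden"])
  cfg$channel_mixing[[parts[1]]][[parts[2]]] <- w
  out <- synth_generate(cfg)
  out$truth$decoy_power_ratio <- decoy_power_ratio
  out
}

#' Write a synthetic fixture to disk
#'
#' Writes `recording.csv` (readable by [read_recording()]), `truth.csv`
#' (clean ECG, artifact, hidden source), `fiducials.csv`, and
#' `config.yaml` holding the full [synth_config()] so the fixture can be
#' regenerated bit-for-bit.
#'
#' @param sim a [synth_generate()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_recording(sim$recording, file.path(dir, "recording.csv"))
  tr <- sim$truth
  utils::write.csv(
    data.frame(clean_ecg = ts_values(tr$clean_ecg),
               artifact = ts_values(tr$artifact),
               hidden = ts_values(tr$hidden_source)),
    file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(data.frame(fiducial = tr$beat_fiducials),
                   file.path(dir, "fiducials.csv"), row.names = FALSE)
  cfg <- tr$config
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"),
                   precision = 17)
  invisible(dir)
}

#' Re-create a synthetic configuration from a fixture directory
#'
#' @param path a `config.yaml` written by [write_fixture()], or the
#'   directory containing it.
#' @return A [synth_config()].
#' @export
read_synth_config <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "config.yaml")
  raw <- yaml::read_yaml(path)
  do.call(synth_config, raw)
}
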