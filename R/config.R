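#' Default pipeline configuration
#'
#' One nested list drives the whole pipeline, with blocks `io` (common
#' rate, alignment), `wavelet` (see [wavelet_config()]), `filter` (see
#' [filter_config()]), `snr` (beat-segment length), and `synth` (defaults
#' for [synth_config()], minus the mandatory seed). Every value can be
#' overridden from a YAML file via [read_config()].
#'
#' @return Nested named list of class `macx_config`.
#' @export
default_config <- function() {
  structure(list(
    io = list(target_rate_hz = 200, align_method = "xcorr",
              align_window_s = 2.0, manual_lags_s = NULL,
              antialias = TRUE),
    wavelet = list(name = "sym16", levels = 10, mode = "reflection",
                   retention = "threshold", threshold_frac = 0.5,
                   min_rho_floor = 0.1),
    filter = list(algorithm = "nlms", order = NULL, mu = NULL, p = 1e-8),
    snr = list(segment_s = 0.6),
    synth = list(rate = 200, duration_s = 60, heart_rate_bpm = 60,
                 beat_jitter_s = 0.02, artifact_gain = 1,
                 n_sensors = 3)
  ), class = "macx_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its [default_config()] value. Unknown top-level blocks are a
#' configuration error.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A `macx_config` list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) {
    stop(config_error(paste0("config file not found: ", path)))
  }
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad) > 0) {
    stop(config_error(paste0("unknown config block(s): ",
                             paste(bad, collapse = ", "))))
  }
  for (block in names(user)) {
    cfg[[block]] <- utils::modifyList(cfg[[block]], user[[block]])
  }
  cfg
}

# internal: classed error constructors so the CLI can map exit codes
config_error <- function(msg) {
  structure(class = c("macx_config_error", "error", "condition"),
            list(message = msg, call = NULL))
}

data_error <- function(msg) {
  structure(class = c("macx_data_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Short content hash of a configuration (audit trail)
#'
#' A 31-bit polynomial hash over the serialized object, printed as hex.
#' Collision resistance is not a goal; the hash only ties a report to the
#' configuration that produced it.
#'
#' @param x any R object.
#' @return An 8-character hex string.
#' @export
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 3))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
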