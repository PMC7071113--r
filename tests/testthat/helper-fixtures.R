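# Shared fixtures, built once per test run and cached (generation is
# deterministic, caching only saves time).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

mk_ts <- function(x, rate = 200, name = "sig") timeseries(x, rate, name)

# band-limited test signal, unit variance
bl_noise <- function(n, rate, band, seed) {
  set.seed(seed)
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x / sd(x)
}

# an inertial sensor whose named axes are given and the rest are fresh noise
mk_sensor <- function(id, given = list(), n = 1000, rate = 200, seed = 99) {
  set.seed(seed)
  axes <- lapply(c(X = "X", Y = "Y", Z = "Z", U = "U", V = "V", W = "W"),
                 function(ax) {
                   v <- if (!is.null(given[[ax]])) given[[ax]] else rnorm(n)
                   timeseries(v, rate, paste0(id, "_", ax))
                 })
  inertial_sensor(id, axes)
}

# single-sensor mixing table: one axis carries the hidden source at `rho`
single_sensor_mixing <- function(rho = 0.9, axis = "Z", id = "s1") {
  axes <- lapply(stats::setNames(nm = c("X", "Y", "Z", "U", "V", "W")),
                 function(a) c(hidden = 0, decoy = 0, noise = 1))
  axes[[axis]] <- mix_weights_for_rho(rho)
  stats::setNames(list(axes), id)
}

default_sim <- function(seed = 1) {
  cached(paste0("sim_", seed), synth_generate(synth_config(seed = seed)))
}

decoy_sim <- function(seed = 1) {
  cached(paste0("decoy_", seed),
         synth_generate_decoy(synth_config(seed = seed)))
}

# recording preprocessed to the common rate and aligned, plus clean truth
# trimmed to the kept ECG span
prepped <- function(sim) {
  rec <- align_recording(resample_recording(sim$recording, 200))
  span <- rec$meta$ecg_span
  list(rec = rec, span = span,
       s = as.numeric(sim$truth$clean_ecg)[span[1]:span[2]],
       fid = {
         f <- sim$truth$beat_fiducials
         f[f >= span[1] & f <= span[2]] - (span[1] - 1L)
       })
}
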