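test_that("generation is deterministic in the seed and requires one", {
  a <- synth_generate(synth_config(seed = 30, duration_s = 10))
  b <- synth_generate(synth_config(seed = 30, duration_s = 10))
  expect_identical(as.numeric(a$recording$ecg), as.numeric(b$recording$ecg))
  expect_identical(as.numeric(a$recording$sensors$left$axes$V),
                   as.numeric(b$recording$sensors$left$axes$V))
  c <- synth_generate(synth_config(seed = 31, duration_s = 10))
  expect_false(identical(as.numeric(a$recording$ecg),
                         as.numeric(c$recording$ecg)))
  expect_error(synth_config(duration_s = 10), "seed is mandatory")
})

test_that("the contaminated ECG decomposes exactly into truth components", {
  sim <- default_sim(1)
  expect_identical(as.numeric(sim$recording$ecg),
                   as.numeric(sim$truth$clean_ecg) +
                     as.numeric(sim$truth$artifact))
  zero <- synth_generate(synth_config(seed = 32, duration_s = 10,
                                      artifact_gain = 0))
  expect_identical(as.numeric(zero$recording$ecg),
                   as.numeric(zero$truth$clean_ecg))
  expect_true(all(as.numeric(zero$truth$artifact) == 0))
})

test_that("artifact power matches the configured gain", {
  sim <- default_sim(1)
  s <- as.numeric(sim$truth$clean_ecg)
  d <- as.numeric(sim$recording$ecg)
  expect_equal(mean((d - s)^2) / stats::var(s), 1, tolerance = 0.01)
})

test_that("planted mixtures realize their target correlations", {
  # w = rho / sqrt(1 - rho^2) on unit-variance components
  for (seed in 1:10) {
    cfg <- synth_config(seed = seed, duration_s = 60, n_sensors = 1,
                        channel_mixing = single_sensor_mixing(0.7, "U"))
    sim <- synth_generate(cfg)
    rho <- pearson_cor(sim$recording$sensors$s1$axes$U,
                       sim$truth$artifact)
    expect_lt(abs(rho - 0.7), 0.05)
  }
})

test_that("every default axis realizes its planted correlation", {
  rho_target <- list(
    left   = c(X = 0.10, Y = 0.20, Z = 0.30, U = 0.05, V = 0.50, W = 0.15),
    middle = c(X = 0.20, Y = 0.30, Z = 0.90, U = 0.15, V = 0.10, W = 0.25),
    right  = c(X = 0.15, Y = 0.40, Z = 0.10, U = 0.20, V = 0.05, W = 0.30))
  for (seed in 1:3) {
    sim <- default_sim(seed)
    hidden <- sim$truth$hidden_source
    for (sid in names(rho_target)) {
      for (ax in names(rho_target[[sid]])) {
        rho <- pearson_cor(sim$recording$sensors[[sid]]$axes[[ax]], hidden)
        expect_lt(abs(rho - rho_target[[sid]][[ax]]), 0.05)
      }
    }
  }
  expect_identical(unname(default_sim(1)$truth$true_winner),
                   c("middle", "Z"))
})

test_that("fiducials sit on the R peaks of the clean ECG", {
  sim <- default_sim(1)
  clean <- as.numeric(sim$truth$clean_ecg)
  for (f in sim$truth$beat_fiducials) {
    lo <- max(1, f - 40); hi <- min(length(clean), f + 40)
    expect_lte(abs(which.max(clean[lo:hi]) + lo - 1 - f), 1)
  }
})

test_that("decoy scenario dilutes the raw reference correlation", {
  for (seed in 1:3) {
    plain <- default_sim(seed)
    decoy <- decoy_sim(seed)
    expect_identical(decoy$truth$decoy_power_ratio, 4)
    rho_plain <- abs(pearson_cor(plain$recording$ecg,
                                 plain$recording$sensors$middle$axes$Z))
    rho_decoy <- abs(pearson_cor(decoy$recording$ecg,
                                 decoy$recording$sensors$middle$axes$Z))
    expect_lt(rho_decoy, rho_plain)
  }
  expect_error(
    synth_generate_decoy(synth_config(seed = 1, decoy_band_hz = c(3, 10))),
    "disjoint")
})

test_that("conditioning is a near no-op when the reference has no
           out-of-band energy to strip", {
  # reference energy confined to the artifact octave (D6 at 200 Hz):
  # no decoy, no broadband noise, so band retention changes nothing
  for (seed in 1:3) {
    n <- 8000
    low <- bl_noise(n, 200, c(1.7, 3), seed)
    inband <- bl_noise(n, 200, c(1.7, 3), seed + 100)
    d <- mk_ts(low + 0.5 * rnorm(n), name = "ecg")
    nu <- mk_ts(low + 0.5 * inband)
    out <- condition_reference(d, nu, wavelet_config(retention = "max"))
    expect_lt(abs(abs(out$rho_conditioned) - abs(out$rho_raw)), 0.05)
  }
})

test_that("fixtures round-trip through disk bit-for-bit", {
  dir <- withr::local_tempdir()
  sim <- synth_generate(synth_config(seed = 33, duration_s = 8))
  write_fixture(sim, dir)
  expect_setequal(list.files(dir), c("recording.csv", "truth.csv",
                                     "fiducials.csv", "config.yaml"))
  cfg2 <- read_synth_config(dir)
  sim2 <- synth_generate(cfg2)
  expect_identical(as.numeric(sim2$recording$ecg),
                   as.numeric(sim$recording$ecg))
  expect_identical(as.numeric(sim2$recording$sensors$right$axes$W),
                   as.numeric(sim$recording$sensors$right$axes$W))
  # the written recording loads cleanly through the standard reader
  back <- expect_no_warning(read_recording(file.path(dir, "recording.csv")))
  expect_equal(as.numeric(back$ecg), as.numeric(sim$recording$ecg),
               tolerance = 1e-12)
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(truth$clean_ecg + truth$artifact,
               as.numeric(sim$recording$ecg), tolerance = 1e-12)
})
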