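test_that("a silent reference leaves the main input untouched", {
  set.seed(1)
  d <- rnorm(500)
  for (alg in c("lms", "nlms")) {
    fit <- adaptive_cancel(d, numeric(500), algorithm = alg)
    expect_equal(as.numeric(fit$e), d)
    expect_equal(as.numeric(fit$y), numeric(500))
    expect_equal(coef(fit), numeric(fit$config$order))
  }
})

test_that("a vanishing step freezes the filter", {
  set.seed(2)
  d <- rnorm(400); x <- rnorm(400)
  for (alg in c("lms", "nlms")) {
    fit <- adaptive_cancel(d, x, algorithm = alg, order = 8, mu = 1e-30)
    expect_lt(max(abs(coef(fit))), 1e-20)
    expect_equal(as.numeric(fit$e), d, tolerance = 1e-12)
  }
})

test_that("e(n) + y(n) = d(n) holds sample-exactly", {
  set.seed(3)
  d <- rnorm(600); x <- 0.8 * d + rnorm(600)
  for (alg in c("lms", "nlms")) {
    fit <- adaptive_cancel(d, x, algorithm = alg, order = 4,
                           mu = if (alg == "lms") 0.005 else 0.2)
    # e is defined as d - y, bit for bit
    expect_identical(as.numeric(fit$e), d - as.numeric(fit$y))
    expect_equal(as.numeric(fit$e) + as.numeric(fit$y), d,
                 tolerance = 1e-15)
  }
})

test_that("both algorithms identify a planted 2-tap system", {
  set.seed(7)
  n <- 20000
  x <- rnorm(n)
  d <- 0.5 * x + 0.25 * c(0, x[-n])
  # white unit-variance input: the Wiener solution equals the planted taps
  lms <- adaptive_cancel(d, x, algorithm = "lms", order = 2, mu = 0.01)
  nlms <- adaptive_cancel(d, x, algorithm = "nlms", order = 2, mu = 0.2)
  expect_lt(max(abs(coef(lms) - c(0.5, 0.25))), 0.02)
  expect_lt(max(abs(coef(nlms) - c(0.5, 0.25))), 0.02)
  expect_lt(convergence_index(nlms$sq_error, 1e-3),
            convergence_index(lms$sq_error, 1e-3))
})

test_that("NLMS is insensitive to reference scale where LMS is not", {
  set.seed(8)
  n <- 8000
  x <- rnorm(n)
  d <- 0.5 * x + 0.25 * c(0, x[-n])
  base <- adaptive_cancel(d, x, algorithm = "nlms", order = 2, mu = 0.2)
  scaled <- adaptive_cancel(100 * d, 100 * x, algorithm = "nlms", order = 2,
                            mu = 0.2)
  c1 <- convergence_index(base$sq_error, 1e-3)
  c2 <- convergence_index(scaled$sq_error / 1e4, 1e-3)
  expect_lt(abs(c2 - c1) / c1, 0.10)
  # fixed-step LMS on the 100x input blows up
  expect_error(adaptive_cancel(100 * d, 100 * x, algorithm = "lms",
                               order = 2, mu = 0.01),
               "diverged")
})

test_that("divergence is reported with the sample index", {
  set.seed(9)
  x <- rnorm(2000)
  err <- tryCatch(adaptive_cancel(rnorm(2000), x, algorithm = "lms",
                                  order = 16, mu = 5),
                  error = function(e) conditionMessage(e))
  expect_match(err, "diverged at sample [0-9]+")
  expect_match(err, "reduce the step size")
})

test_that("the filter is strictly causal", {
  set.seed(10)
  d <- rnorm(300); x <- rnorm(300)
  x2 <- x
  x2[201:300] <- rnorm(100) * 10
  for (alg in c("lms", "nlms")) {
    f1 <- adaptive_cancel(d, x, algorithm = alg, order = 8, mu = 1e-3)
    f2 <- adaptive_cancel(d, x2, algorithm = alg, order = 8, mu = 1e-3)
    expect_identical(as.numeric(f1$y)[1:200], as.numeric(f2$y)[1:200])
  }
})

test_that("explicit initial weights are honoured and validated", {
  set.seed(11)
  x <- rnorm(100)
  fit <- adaptive_cancel(0.5 * x, x, config = filter_config(
    "nlms", order = 2, mu = 1e-30, init_weights = c(0.5, 0)))
  expect_equal(as.numeric(fit$e), numeric(100), tolerance = 1e-10)
  expect_error(filter_config("nlms", order = 4, init_weights = c(1, 2)),
               "length")
  expect_error(filter_config("nlms", mu = -1), "mu > 0")
})

test_that("a correlated reference cancels a planted artifact mixture", {
  set.seed(12)
  n <- 8000
  x <- rnorm(n)
  h <- c(0.5, 0.3, 0.2)
  artifact <- as.numeric(stats::filter(x, h, method = "convolution",
                                       sides = 1))
  artifact[is.na(artifact)] <- 0
  s <- 0.3 * sin(2 * pi * (1:n) / 200)
  d <- s + artifact
  fit <- adaptive_cancel(d, x, algorithm = "nlms")
  ti <- (floor(0.75 * n) + 1):n
  e <- as.numeric(fit$e)
  expect_lt(mean((e[ti] - s[ti])^2), 0.1 * mean((d - s)^2))
})

test_that("an uncorrelated reference does bounded harm", {
  set.seed(13)
  n <- 8000
  artifact <- bl_noise(n, 200, c(0.5, 5), 13)
  s <- 0.3 * sin(2 * pi * (1:n) / 200)
  d <- s + artifact
  x <- rnorm(n)  # independent of the artifact
  fit <- adaptive_cancel(d, x, algorithm = "nlms")
  ti <- (floor(0.75 * n) + 1):n
  e <- as.numeric(fit$e)
  expect_lt(mean((e[ti] - s[ti])^2), 1.5 * mean((d - s)^2))
})

test_that("degenerate full-correlation reference cancels everything", {
  set.seed(14)
  d <- bl_noise(4000, 200, c(0.5, 5), 14)
  fit <- adaptive_cancel(d, d, algorithm = "nlms", order = 1, mu = 0.5)
  tail_mse <- mean(fit$sq_error[3001:4000])
  expect_lt(tail_mse, 0.05 * mean(d^2))
})

test_that("convergence_index finds the first window under threshold", {
  sq <- c(rep(1, 150), rep(1e-6, 250))
  idx <- convergence_index(sq, 1e-3, window = 100)
  expect_true(idx > 150 && idx <= 260)
  expect_true(is.na(convergence_index(rep(1, 300), 1e-3)))
  expect_true(is.na(convergence_index(rep(1, 50), 1e-3, window = 100)))
})

test_that("anc accessors expose the fit components", {
  set.seed(15)
  d <- mk_ts(rnorm(300), rate = 200, name = "ecg")
  x <- mk_ts(rnorm(300), rate = 200)
  fit <- adaptive_cancel(d, x, algorithm = "nlms", order = 4)
  expect_s3_class(fit, "anc")
  expect_identical(residuals(fit), fit$e)
  expect_identical(fitted(fit), fit$y)
  expect_length(coef(fit), 4L)
  expect_equal(ts_rate(residuals(fit)), 200)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.anc")
  expect_equal(sm$mse_total, mean(fit$sq_error))
})
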