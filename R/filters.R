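#' Adaptive filter settings
#'
#' @param algorithm `"lms"` or `"nlms"`.
#' @param order number of taps. Defaults per algorithm: 32 for NLMS
#'   (160 ms at 200 Hz, spanning the plausible electrode-motion impulse
#'   response) and 2 for LMS. The asymmetry is a stability requirement,
#'   not a preference: with the explicit factor-2 update, mean-square
#'   stability for a unit-variance reference needs `2 * mu * order`
#'   well below the Gaussian-theory 1/3 bound, and the heavy-tailed
#'   error signal of an ECG (R-wave spikes) erodes the margin further —
#'   longer LMS filters burst intermittently at `mu = 0.03`. NLMS's
#'   normalization removes the order dependence.
#' @param mu step size; defaults to 0.03 for LMS and 0.2 for NLMS. Note
#'   the LMS update uses `2 * mu * e(n) * u(n)` (the factor 2 belongs to
#'   the gradient of the squared error and is kept explicit), while the
#'   NLMS update uses `mu / (p + u'u) * e(n) * u(n)` with no factor 2;
#'   users comparing against the textbook convention without the factor 2
#'   should halve/double `mu` accordingly.
#' @param p NLMS denominator regularizer, a small positive number keeping
#'   the normalized step finite when the tap vector is silent
#'   (default 1e-8).
#' @param init_weights `"zeros"` or an explicit numeric vector of length
#'   `order`.
#' @return A list of class `macx_fltcfg`.
#' @export
filter_config <- function(algorithm = c("nlms", "lms"), order = NULL,
                          mu = NULL, p = 1e-8, init_weights = "zeros") {
  algorithm <- match.arg(algorithm)
  if (is.null(mu)) mu <- if (algorithm == "lms") 0.03 else 0.2
  if (is.null(order)) order <- if (algorithm == "lms") 2 else 32
  stopifnot(mu > 0, p > 0, order >= 1)
  if (is.numeric(init_weights) && length(init_weights) != order) {
    stop("init_weights must have length `order`")
  }
  structure(list(algorithm = algorithm, order = as.integer(order),
                 mu = mu, p = p, init_weights = init_weights),
            class = "macx_fltcfg")
}

#' Adaptive noise cancellation (LMS / NLMS)
#'
#' Fits a transversal adaptive filter that estimates, sample by sample, the
#' motion-artifact component of the main input `d` from the reference `x`,
#' and subtracts it. At sample n the tap input is
#' `u(n) = (x(n), x(n-1), ..., x(n-order+1))` (zero pre-padded), the
#' artifact estimate is `y(n) = w'u(n)`, the cleaned output is
#' `e(n) = d(n) - y(n)`, and the weights update by stochastic gradient:
#' LMS `w <- w + 2 mu e(n) u(n)`; NLMS `w <- w + mu/(p + u'u) e(n) u(n)`.
#' The NLMS normalization makes convergence insensitive to the reference's
#' scale and shortens the time to reach steady state. The filter is
#' strictly causal: `y(n)` depends only on reference samples up to n and,
#' through the weights, on earlier errors.
#'
#' @param d main input (contaminated ECG), [timeseries()] or numeric.
#' @param x reference input, same length as `d`.
#' @param config a [filter_config()]; or pass `algorithm`/`order`/`mu`/`p`
#'   directly.
#' @param keep_weights_trace store the full weight trajectory (an
#'   `n x order` matrix)? Off by default (memory).
#' @inheritParams filter_config
#' @return An object of class `anc` with components `y` (artifact
#'   estimate), `e` (cleaned ECG), `weights` (final taps, most recent
#'   first), `sq_error` (per-sample `e(n)^2`), `config`, and optionally
#'   `weights_trace`. Access with [fitted()], [residuals()], [coef()].
#'   `e + y == d` holds sample-exactly by construction.
#' @examples
#' set.seed(7)
#' x <- rnorm(4000)
#' d <- 0.5 * x + 0.25 * c(0, x[-4000])
#' fit <- adaptive_cancel(d, x, algorithm = "nlms", order = 2)
#' round(coef(fit), 3) # close to c(0.5, 0.25)
#' @export
adaptive_cancel <- function(d, x, config = NULL,
                            algorithm = c("nlms", "lms"), order = NULL,
                            mu = NULL, p = 1e-8,
                            keep_weights_trace = FALSE) {
  if (is.null(config)) {
    config <- filter_config(match.arg(algorithm), order, mu, p)
  }
  dv <- as_samples(d)
  xv <- as_samples(x)
  if (length(dv) != length(xv)) {
    stop("length mismatch: d has ", length(dv), " samples, x has ",
         length(xv))
  }
  n <- length(dv)
  m <- config$order
  w <- if (identical(config$init_weights, "zeros")) numeric(m)
       else as.numeric(config$init_weights)
  xpad <- c(numeric(m - 1), xv)  # xpad[n + m - 1] == x(n)
  y <- numeric(n)
  e <- numeric(n)
  trace <- if (keep_weights_trace) matrix(NA_real_, n, m) else NULL
  lms <- config$algorithm == "lms"
  mu_ <- config$mu
  p_ <- config$p
  for (i in seq_len(n)) {
    u <- xpad[(i + m - 1):i]  # current sample first, then the past
    y[i] <- sum(w * u)
    e[i] <- dv[i] - y[i]
    gain <- if (lms) 2 * mu_ * e[i] else mu_ * e[i] / (p_ + sum(u * u))
    w <- w + gain * u
    if (any(abs(w) > 1e8) || any(!is.finite(w))) {
      stop("adaptive filter diverged at sample ", i,
           " (|weight| exceeded 1e8); reduce the step size mu (",
           format(mu_), ")")
    }
    if (keep_weights_trace) trace[i, ] <- w
  }
  out_ts <- function(v, nm) {
    if (inherits(d, "macx_ts")) ts_replace(d, v, name = nm)
    else timeseries(v, rate = 1, name = nm)
  }
  structure(list(y = out_ts(y, "artifact_estimate"),
                 e = out_ts(e, "cleaned_ecg"),
                 weights = w, sq_error = e^2,
                 weights_trace = trace, config = config,
                 call = match.call()),
            class = "anc")
}

#' @export
print.anc <- function(x, ...) {
  cat(sprintf("<anc: %s, order %d, mu = %g, %d samples>\n",
              toupper(x$config$algorithm), x$config$order, x$config$mu,
              length(x$e)))
  cat("final weights (most recent tap first):\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
summary.anc <- function(object, tail_frac = 0.25, ...) {
  n <- length(object$e)
  tail_idx <- seq.int(max(1L, floor((1 - tail_frac) * n) + 1L), n)
  out <- list(algorithm = object$config$algorithm,
              order = object$config$order, mu = object$config$mu,
              n = n,
              mse_total = mean(object$sq_error),
              mse_tail = mean(object$sq_error[tail_idx]),
              weight_norm = sqrt(sum(object$weights^2)))
  class(out) <- "summary.anc"
  out
}

#' @export
print.summary.anc <- function(x, ...) {
  cat(sprintf("%s adaptive canceller (order %d, mu = %g)\n",
              toupper(x$algorithm), x$order, x$mu))
  cat(sprintf("  samples: %d\n  mean square error: %.4g (tail: %.4g)\n",
              x$n, x$mse_total, x$mse_tail))
  cat(sprintf("  final weight norm: %.4g\n", x$weight_norm))
  invisible(x)
}

#' @export
coef.anc <- function(object, ...) object$weights

#' @export
fitted.anc <- function(object, ...) object$y

#' Cleaned ECG from an adaptive cancellation fit
#'
#' The residual of the artifact regression is the signal of interest:
#' `e = d - y`, the ECG with the estimated motion artifact removed.
#' @param object an [adaptive_cancel()] fit.
#' @param ... unused.
#' @return The cleaned [timeseries()].
#' @export
residuals.anc <- function(object, ...) object$e

#' @export
plot.anc <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  tt <- ts_times(x$e)
  d <- ts_values(x$e) + ts_values(x$y)
  graphics::plot(tt, d, type = "l", col = "grey50", xlab = "time [s]",
                 ylab = "amplitude", main = "main input and cleaned output",
                 ...)
  graphics::lines(tt, ts_values(x$e), col = "firebrick")
  graphics::legend("topright", c("d(n)", "e(n)"), lty = 1,
                   col = c("grey50", "firebrick"), bty = "n")
  graphics::plot(tt, x$sq_error, type = "l", log = "y", xlab = "time [s]",
                 ylab = "e(n)^2", main = "squared error")
  invisible(x)
}

#' Samples needed to reach a mean-square-error threshold
#'
#' Convergence diagnostic: the first sample index at which the trailing
#' moving average (window `window` samples) of a squared error drops to
#' `threshold` or below.
#'
#' @param sq_error numeric vector of per-sample squared errors (e.g.
#'   `fit$sq_error`, or squared deviation from a known clean signal).
#' @param threshold MSE threshold.
#' @param window moving-average window in samples (default 100).
#' @return Integer index, or `NA` if the threshold is never reached.
#' @export
convergence_index <- function(sq_error, threshold, window = 100) {
  n <- length(sq_error)
  if (n < window) return(NA_integer_)
  ma <- stats::filter(sq_error, rep(1 / window, window), sides = 1)
  hit <- which(!is.na(ma) & ma <= threshold)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}
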