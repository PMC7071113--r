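#' Run the full cancellation pipeline on one recording
#'
#' Executes resample (common rate, cubic spline) -> align (cross-correlation
#' or manual lags) -> reference selection (best of 7 candidates x M
#' sensors) -> wavelet conditioning of the reference -> adaptive
#' cancellation -> paired eigenvalue SNR of the ECG before and after.
#' `wavelet = FALSE` bypasses conditioning and feeds the raw selected
#' channel to the canceller (the ablation arm).
#'
#' @param rec a [recording()].
#' @param config a [default_config()]-shaped list.
#' @param wavelet condition the reference before cancelling?
#'   (default `TRUE`).
#' @param fiducials optional known beat indices (on the common-rate time
#'   base) for SNR segmentation; default: detector on the cleaned output.
#' @return Object of class `macx_run`: `cleaned` ([timeseries()]),
#'   `fit` (the [adaptive_cancel()] object), `selection`, `conditioning`
#'   (`NULL` when bypassed), `snr`, and `report` (flat, JSON-ready
#'   summary).
#' @export
run_pipeline <- function(rec, config = default_config(), wavelet = TRUE,
                         fiducials = NULL) {
  stopifnot(inherits(rec, "macx_recording"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  rate <- config$io$target_rate_hz
  rec <- stage("resample",
               resample_recording(rec, rate, config$io$antialias))
  rec <- stage("align",
               align_recording(rec, config$io$align_method,
                               config$io$manual_lags_s,
                               config$io$align_window_s))
  span <- rec$meta$ecg_span
  if (!is.null(fiducials) && !is.null(span)) {
    # supplied beat indices refer to the pre-alignment time base
    fiducials <- fiducials[fiducials >= span[1] & fiducials <= span[2]] -
      (span[1] - 1L)
  }
  sel <- stage("select", select_reference(rec$ecg, rec$sensors))
  wcfg <- wavelet_config(config$wavelet$name, config$wavelet$levels,
                         config$wavelet$mode, config$wavelet$retention,
                         config$wavelet$threshold_frac,
                         config$wavelet$min_rho_floor)
  cond <- NULL
  if (wavelet) {
    cond <- stage("condition", condition_reference(rec$ecg, sel$nu, wcfg))
    x <- cond$x
  } else {
    x <- sel$nu
  }
  fcfg <- filter_config(config$filter$algorithm, config$filter$order,
                        config$filter$mu, config$filter$p)
  # standardize the reference: inertial units (m/s^2, deg/s) are arbitrary
  # relative to the ECG's, and the printed step sizes presuppose a
  # unit-scale reference; correlation-based selection is unaffected
  xs <- ts_replace(x, as.vector(scale(ts_values(x))))
  fit <- stage("cancel", adaptive_cancel(rec$ecg, xs, fcfg))
  n_seg <- round(config$snr$segment_s * rate)
  snr <- stage("snr", snr_report(rec$ecg, fit$e, fiducials, n_seg))

  report <- list(
    selection = list(sensor = sel$winner_sensor,
                     channel = sel$winner_channel,
                     rho = sel$winner_rho),
    wavelet_conditioning = wavelet,
    retained_bands = if (wavelet) cond$retained else character(0),
    rho_raw = if (wavelet) cond$rho_raw else sel$winner_rho,
    rho_conditioned = if (wavelet) cond$rho_conditioned else sel$winner_rho,
    algorithm = fcfg$algorithm,
    snr_before = snr$before$snr,
    snr_after = snr$after$snr,
    snr_delta = snr$delta,
    n_beats = length(snr$fiducials),
    n_samples = length(rec$ecg),
    ecg_span = span,
    rate_hz = rate,
    applied_lags_s = rec$meta$applied_lags$seconds,
    config_hash = config_hash(config),
    versions = list(macx = as.character(utils::packageVersion("macx")),
                    r = paste(R.version$major, R.version$minor, sep = ".")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(cleaned = fit$e, fit = fit, selection = sel,
                 conditioning = cond, snr = snr, report = report),
            class = "macx_run")
}

#' @export
print.macx_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("<macx_run: %s%s on %d samples @ %g Hz>\n",
              toupper(r$algorithm),
              if (r$wavelet_conditioning) " + wavelet reference" else
                " (raw reference)",
              r$n_samples, r$rate_hz))
  cat(sprintf("  reference: %s/%s, rho raw %.4f -> conditioned %.4f\n",
              r$selection$sensor, r$selection$channel, r$rho_raw,
              r$rho_conditioned))
  cat(sprintf("  SNR: %.4f -> %.4f (delta %+.4f, %d beats)\n",
              r$snr_before, r$snr_after, r$snr_delta, r$n_beats))
  invisible(x)
}

#' @export
summary.macx_run <- function(object, ...) {
  print(object)
  cat("  retained bands:",
      paste(object$report$retained_bands, collapse = ", "), "\n")
  print(summary(object$fit))
  invisible(object$report)
}

#' @export
plot.macx_run <- function(x, ...) {
  plot(x$fit, ...)
}

#' Run the 2 x 2 comparison grid: {LMS, NLMS} x {raw, conditioned}
#'
#' Mirrors the method-comparison design: each algorithm runs once with the
#' raw selected reference and once with the wavelet-conditioned reference,
#' on the same recording and the same beat fiducials. A failing cell is
#' reported as `NA` with its error message; the other cells still run.
#'
#' @inheritParams run_pipeline
#' @return A data.frame with one row per cell: `algorithm`, `reference`,
#'   `rho`, `snr_before`, `snr_after`, `snr_delta`, `error`. The full
#'   `macx_run` objects are attached as attribute `"runs"`.
#' @export
run_matrix <- function(rec, config = default_config(), fiducials = NULL) {
  cells <- expand.grid(algorithm = c("lms", "nlms"),
                       reference = c("raw", "conditioned"),
                       stringsAsFactors = FALSE)
  runs <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- config
    cfg$filter$algorithm <- cells$algorithm[i]
    res <- tryCatch(
      run_pipeline(rec, cfg, wavelet = cells$reference[i] == "conditioned",
                   fiducials = fiducials),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(cells[i, ], rho = NA_real_,
                              snr_before = NA_real_, snr_after = NA_real_,
                              snr_delta = NA_real_,
                              error = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      runs[[i]] <- res
      r <- res$report
      rows[[i]] <- data.frame(cells[i, ], rho = r$rho_conditioned,
                              snr_before = r$snr_before,
                              snr_after = r$snr_after,
                              snr_delta = r$snr_delta, error = "",
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "runs") <- runs
  out
}

#' Write a pipeline report as JSON
#'
#' @param report the `report` element of a [run_pipeline()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Check that a report carries every required field
#'
#' Validates a pipeline report against the field list shipped in
#' `inst/schema/report-schema.json`.
#'
#' @param report a report list (e.g. re-read from JSON).
#' @return `TRUE`, or an error naming the missing field(s).
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema", "report-schema.json",
                                            package = "macx"))
  missing <- setdiff(unlist(schema$required), names(report))
  if (length(missing) > 0) {
    stop("report is missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  TRUE
}
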