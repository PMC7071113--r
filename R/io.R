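#' Read a multi-channel recording from CSV
#'
#' Expects a comma-separated file ('.' decimal, UTF-8) with a mandatory
#' header row naming the channels: one ECG column (default `ecg`) and, per
#' sensor, six axis columns named `<sensor_id>_<axis>` with axis in
#' X, Y, Z, U, V, W. A `time` column, if present, is ignored (rates come
#' from configuration, never inferred from timestamps). Lines starting with
#' `#` are header comments; `write_recording()` stores per-channel rates
#' there as `# rates: ecg=200,left=100,...`, and `read_recording()` falls
#' back on them when `rates` is not supplied.
#'
#' Channels recorded at different rates have different lengths; shorter
#' columns are padded with empty trailing cells, which are trimmed on read.
#' An empty or non-numeric cell in the interior of a channel is a parse
#' error: missing samples are rejected, not imputed.
#'
#' @param path CSV file path.
#' @param rates named list/vector of sampling rates in Hz: one entry `ecg`
#'   and one per sensor id (all six axes of a sensor share its rate).
#'   Defaults to the `# rates:` header comment when present.
#' @param ecg_col name of the ECG column (default `"ecg"`).
#' @return A [recording()] with raw, unresampled channels; the
#'   column-to-role mapping and the rate source are recorded in `$meta`.
#' @seealso [write_recording()], [resample_recording()], [align_recording()]
#' @export
read_recording <- function(path, rates = NULL, ecg_col = "ecg") {
  if (!file.exists(path)) stop("no such file: ", path)
  header_rates <- read_rate_comment(path)
  if (is.null(rates)) rates <- header_rates
  raw <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  cols <- names(raw)
  if (!(ecg_col %in% cols)) {
    stop("format error: required column '", ecg_col, "' not found in ", path)
  }

  parse_col <- function(nm) {
    v <- raw[[nm]]
    # trim trailing empties (shorter channel in a mixed-rate file)
    nonempty <- which(v != "")
    if (length(nonempty) == 0L) stop("channel '", nm, "' is empty in ", path)
    v <- v[seq_len(max(nonempty))]
    if (any(v == "")) {
      stop("parse error: empty cell inside channel '", nm, "' at row ",
           which(v == "")[1L])
    }
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | is.nan(num))
    if (length(bad) > 0) {
      stop("parse error: non-numeric or NaN value '", v[bad[1L]],
           "' in channel '", nm, "' at row ", bad[1L])
    }
    num
  }

  sensor_cols <- grep("^(.+)_([XYZUVW])$", setdiff(cols, c("time", ecg_col)),
                      value = TRUE)
  sids <- unique(sub("^(.+)_([XYZUVW])$", "\\1", sensor_cols))
  if (length(sids) == 0L) stop("format error: no sensor axis columns found")

  rate_of <- function(id) {
    if (is.null(rates) || is.null(rates[[id]])) {
      stop("no sampling rate given for channel group '", id,
           "' (supply `rates` or a '# rates:' header comment)")
    }
    as.numeric(rates[[id]])
  }

  ecg <- timeseries(parse_col(ecg_col), rate = rate_of("ecg"), name = "ecg")
  sensors <- lapply(sids, function(sid) {
    have <- paste0(sid, "_", AXIS_NAMES) %in% cols
    if (!all(have)) {
      stop("schema error: sensor '", sid, "' is missing axis column(s): ",
           paste(AXIS_NAMES[!have], collapse = ", "))
    }
    r <- rate_of(sid)
    axes <- lapply(AXIS_NAMES, function(ax) {
      timeseries(parse_col(paste0(sid, "_", ax)), rate = r,
                 name = paste0(sid, "_", ax))
    })
    names(axes) <- AXIS_NAMES
    inertial_sensor(sid, axes)
  })
  recording(ecg, sensors,
            meta = list(source = path, ecg_col = ecg_col,
                        sensor_ids = sids,
                        rates = lapply(stats::setNames(c("ecg", sids),
                                                       c("ecg", sids)),
                                       rate_of)))
}

# internal: parse '# rates: a=1,b=2' comment from the first comment lines
read_rate_comment <- function(path) {
  head_lines <- readLines(path, n = 10L, warn = FALSE)
  rl <- grep("^#\\s*rates:", head_lines, value = TRUE)
  if (length(rl) == 0L) return(NULL)
  body <- sub("^#\\s*rates:\\s*", "", rl[1L])
  parts <- strsplit(strsplit(body, ",")[[1]], "=")
  vals <- lapply(parts, function(p) as.numeric(p[2L]))
  names(vals) <- vapply(parts, function(p) trimws(p[1L]), character(1))
  vals
}

#' Write a recording to CSV
#'
#' One column per channel (`ecg`, then `<sid>_<axis>` per sensor); the
#' per-channel sampling rates go into a `# rates:` header comment so the
#' file round-trips through [read_recording()] without a sidecar. Channels
#' shorter than the longest one get empty trailing cells. Samples are
#' written with 17 significant digits, so a read/write round trip
#' reproduces them to double precision.
#'
#' @param rec a [recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "macx_recording"))
  chans <- recording_channels(rec)
  lens <- vapply(chans, length, integer(1))
  if (any(lens == 0L)) stop("refusing to write zero-length channel")
  n <- max(lens)
  cells <- lapply(chans, function(ts) {
    v <- sprintf("%.17g", ts_values(ts))
    c(v, rep("", n - length(v)))
  })
  rate_items <- c(sprintf("ecg=%g", ts_rate(rec$ecg)),
                  vapply(rec$sensors, function(s)
                    sprintf("%s=%g", s$sensor_id, ts_rate(s$axes$X)),
                    character(1)))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  writeLines(paste0("# rates: ", paste(rate_items, collapse = ",")), con)
  writeLines(paste(names(chans), collapse = ","), con)
  rows <- do.call(paste, c(cells, sep = ","))
  writeLines(rows, con)
  invisible(path)
}
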