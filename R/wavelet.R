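# Orthogonal scaling (low-pass) filters, unit-scale DWT normalisation
# (sum of squares = 1). Daubechies extremal-phase (db) and
# least-asymmetric/symlet (sym) families, plus Haar.
WT_SCALING_FILTERS <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
          0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  sym8 = c(-0.0033824159510061256, -0.0005421323317911481,
           0.03169508781149298, 0.007607487324917605, -0.1432942383508097,
           -0.061273359067658524, 0.4813596512583722, 0.7771857517005235,
           0.3644418948353314, -0.05194583810770904, -0.027219029917056003,
           0.049137179673607506, 0.003808752013890615, -0.01495225833704823,
           -0.0003029205147213668, 0.0018899503327594609),
  sym16 = c(6.230006701220761e-06, -3.113556407621969e-06,
            -0.00010943147929529757, 2.8078582128442894e-05,
            0.0008523547108047095, -0.0001084456223089688,
            -0.0038809122526038786, 0.0007182119788317892,
            0.012666731659857348, -0.0031265171722710075,
            -0.031051202843553064, 0.004869274404904607,
            0.032333091610663785, -0.06698304907021778,
            -0.034574228416972504, 0.39712293362064416, 0.7565249878756971,
            0.47534280601152273, -0.054040601387606135, -0.15959219218520598,
            0.03072113906330156, 0.07803785290341991, -0.003510275068374009,
            -0.024952758046290123, 0.001359844742484172,
            0.0069377611308027096, -0.00022211647621176323,
            -0.0013387206066921965, 3.656592483348223e-05,
            0.00016545679579108483, -5.396483179315242e-06,
            -1.0797982104319795e-05)
)

# internal: MODWT filter pair (rescaled by 1/sqrt(2)); h is the quadrature
# mirror of g: h_l = (-1)^l g_{L-1-l}
wt_filters <- function(wavelet) {
  g <- WT_SCALING_FILTERS[[wavelet]]
  if (is.null(g)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(WT_SCALING_FILTERS), collapse = ", "))
  }
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)
  list(g = g / sqrt(2), h = h / sqrt(2))
}

# internal: circular shift so that out[t] = x[(t - s) mod N], 1-indexed
wt_shift <- function(x, s) {
  n <- length(x)
  x[((seq_len(n) - 1 - s) %% n) + 1]
}

#' Maximal-overlap discrete wavelet transform (pyramid algorithm)
#'
#' Undecimated orthonormal wavelet transform: every level keeps full signal
#' length, so band signals can be correlated sample-for-sample against a
#' second channel, and the multiresolution analysis is additive for any
#' signal length. `mode = "reflection"` (default) concatenates the signal
#' with its time reverse before the circular transform and truncates
#' afterwards, which suppresses wrap-around edge artifacts; `"periodic"`
#' operates on the signal as-is.
#'
#' @param x numeric vector or [timeseries()].
#' @param wavelet filter name; one of `haar`, `db2`, `db4`, `sym8`,
#'   `sym16` (default).
#' @param levels decomposition depth L; clamped (with a warning) to the
#'   admissible maximum `floor(log2(n))`.
#' @param mode `"reflection"` or `"periodic"` boundary handling.
#' @return List with `W` (n x L matrix of wavelet coefficients, columns
#'   levels 1..L), `V` (level-L scaling coefficients), and the settings.
#' @seealso [wt_mra()] for the additive band decomposition.
#' @export
wt_modwt <- function(x, wavelet = "sym16", levels = 10,
                     mode = c("reflection", "periodic")) {
  mode <- match.arg(mode)
  x0 <- as_samples(x)
  n0 <- length(x0)
  if (n0 < 2L) stop("signal too short for wavelet decomposition")
  lmax <- floor(log2(n0))
  if (levels > lmax) {
    warning("level ", levels, " too deep for ", n0,
            " samples; clamped to max admissible level ", lmax)
    levels <- lmax
  }
  if (levels < 1L) stop("levels must be >= 1")
  f <- wt_filters(wavelet)
  xe <- if (mode == "reflection") c(x0, rev(x0)) else x0
  n <- length(xe)
  W <- matrix(0, n, levels)
  V <- xe
  for (j in seq_len(levels)) {
    s <- 2^(j - 1)
    Wj <- numeric(n)
    Vj <- numeric(n)
    for (l in seq_along(f$g)) {
      shifted <- wt_shift(V, s * (l - 1))
      Wj <- Wj + f$h[l] * shifted
      Vj <- Vj + f$g[l] * shifted
    }
    W[, j] <- Wj
    V <- Vj
  }
  list(W = W, V = V, wavelet = wavelet, levels = levels, mode = mode,
       n = n0)
}

# internal: one inverse pyramid stage
wt_istage <- function(Wj, Vj, f, s) {
  out <- numeric(length(Vj))
  for (l in seq_along(f$g)) {
    out <- out + f$h[l] * wt_shift(Wj, -s * (l - 1)) +
      f$g[l] * wt_shift(Vj, -s * (l - 1))
  }
  out
}

#' Invert a maximal-overlap wavelet transform
#'
#' @param wt result of [wt_modwt()].
#' @return Numeric vector reconstructing the original signal.
#' @export
wt_imodwt <- function(wt) {
  f <- wt_filters(wt$wavelet)
  V <- wt$V
  for (j in rev(seq_len(wt$levels))) {
    V <- wt_istage(wt$W[, j], V, f, 2^(j - 1))
  }
  V[seq_len(wt$n)]
}

#' Additive multiresolution analysis
#'
#' Reconstructs, for each level, the full-length band signal obtained by
#' zeroing every other level's coefficients and inverting the transform.
#' The L detail bands plus the level-L smooth sum to the input signal
#' exactly (to round-off), for any input length.
#'
#' @inheritParams wt_modwt
#' @return An `n x (levels + 1)` matrix; columns `D1` (finest octave,
#'   rate/4..rate/2) through `DL`, then the smooth `AL`.
#' @export
wt_mra <- function(x, wavelet = "sym16", levels = 10,
                   mode = c("reflection", "periodic")) {
  wt <- wt_modwt(x, wavelet, levels, mode)
  f <- wt_filters(wt$wavelet)
  nfull <- nrow(wt$W)
  zero <- numeric(nfull)
  L <- wt$levels
  out <- matrix(0, wt$n, L + 1)
  colnames(out) <- c(paste0("D", seq_len(L)), paste0("A", L))
  for (b in seq_len(L + 1)) {
    V <- if (b == L + 1) wt$V else zero
    for (j in rev(seq_len(L))) {
      Wj <- if (j == b) wt$W[, j] else zero
      V <- wt_istage(Wj, V, f, 2^(j - 1))
    }
    out[, b] <- V[seq_len(wt$n)]
  }
  out
}

#' Wavelet-conditioning settings
#'
#' @param wavelet filter name (default `"sym16"`).
#' @param levels decomposition depth (default 10).
#' @param mode boundary handling, `"reflection"` (default) or
#'   `"periodic"`.
#' @param retention `"max"` keeps the single band best correlated with the
#'   ECG; `"threshold"` keeps every band whose absolute correlation is at
#'   least `threshold_frac` times the best band's.
#' @param threshold_frac retention threshold as a fraction of the maximum
#'   absolute band correlation (default 0.5).
#' @param min_rho_floor below this absolute correlation for the best band,
#'   [condition_reference()] warns that the reference is weak
#'   (default 0.1).
#' @return A list of class `macx_wtcfg`.
#' @export
wavelet_config <- function(wavelet = "sym16", levels = 10,
                           mode = c("reflection", "periodic"),
                           retention = c("max", "threshold"),
                           threshold_frac = 0.5, min_rho_floor = 0.1) {
  mode <- match.arg(mode)
  retention <- match.arg(retention)
  stopifnot(levels >= 1, threshold_frac >= 0, threshold_frac <= 1)
  structure(list(wavelet = wavelet, levels = levels, mode = mode,
                 retention = retention, threshold_frac = threshold_frac,
                 min_rho_floor = min_rho_floor),
            class = "macx_wtcfg")
}

#' Decompose the raw reference into wavelet bands scored against the ECG
#'
#' Splits the selected reference channel `nu` into `levels` detail bands
#' plus the smooth (each a full-length signal; together they sum back to
#' `nu`), and computes each band's Pearson correlation with the main input
#' `d`. Band order in the result is smooth first (`A<L>`), then details
#' coarse to fine (`D<L>` ... `D1`).
#'
#' @param nu the selected raw reference channel ([timeseries()]).
#' @param d the main input ECG, same length as `nu`.
#' @param cfg a [wavelet_config()].
#' @return Object of class `macx_bands`: list with `labels`, `signals`
#'   (list of [timeseries()]), `rho`, `levels`, `config`, `input_name`.
#' @export
decompose_bands <- function(nu, d, cfg = wavelet_config()) {
  stopifnot(inherits(nu, "macx_ts"), inherits(d, "macx_ts"))
  if (length(nu) != length(d)) {
    stop("nu and d must have equal length (", length(nu), " vs ",
         length(d), ")")
  }
  m <- wt_mra(nu, cfg$wavelet, cfg$levels, cfg$mode)
  L <- ncol(m) - 1L
  order_idx <- c(L + 1L, rev(seq_len(L)))  # A_L, D_L, ..., D_1
  labels <- colnames(m)[order_idx]
  signals <- lapply(order_idx, function(i) {
    ts_replace(nu, m[, i], name = paste0(ts_name(nu), ".", colnames(m)[i]))
  })
  rho <- vapply(signals, function(s) pearson_cor(d, s), numeric(1))
  structure(list(labels = labels, signals = signals, rho = rho,
                 levels = L, config = cfg, input_name = ts_name(nu)),
            class = "macx_bands")
}

#' @export
print.macx_bands <- function(x, ...) {
  cat(sprintf("<macx_bands: %d bands of '%s' (%s, L=%d)>\n",
              length(x$labels), x$input_name, x$config$wavelet, x$levels))
  print(data.frame(band = x$labels, rho = round(x$rho, 4)), row.names = FALSE)
  invisible(x)
}

#' Assemble the conditioned reference from correlated bands
#'
#' Retention `"max"` returns the single band with the largest absolute
#' correlation with the ECG, bit-for-bit; `"threshold"` sums all bands
#' whose absolute correlation reaches `threshold_frac` of the maximum
#' (with `threshold_frac = 0` this reconstructs the raw reference).
#' Bands with undefined (zero-variance) correlation rank as 0.
#'
#' @param bd a [decompose_bands()] result.
#' @param cfg a [wavelet_config()]; defaults to the one stored in `bd`.
#' @return List: `x` (the conditioned reference, [timeseries()]) and
#'   `retained` (character vector of band labels).
#' @export
build_reference <- function(bd, cfg = bd$config) {
  stopifnot(inherits(bd, "macx_bands"))
  if (all(is.na(bd$rho))) {
    stop("reference unusable: every wavelet band has undefined ",
         "correlation with the main input")
  }
  score <- abs(ifelse(is.na(bd$rho), 0, bd$rho))
  if (cfg$retention == "max") {
    keep <- which.max(score)
  } else {
    keep <- which(score >= cfg$threshold_frac * max(score))
  }
  xsig <- Reduce(`+`, lapply(bd$signals[keep], ts_values))
  x <- ts_replace(bd$signals[[1L]], xsig,
                  name = paste0(bd$input_name, ".conditioned"))
  list(x = x, retained = bd$labels[keep])
}

#' Wavelet-condition the selected reference channel
#'
#' The composition [decompose_bands()] then [build_reference()]: strips
#' from the raw reference the frequency bands that carry sensor vibration
#' unrelated to electrode motion, keeping only the bands correlated with
#' the contaminated ECG. Warns when even the best band's absolute
#' correlation falls below `cfg$min_rho_floor`.
#'
#' @inheritParams decompose_bands
#' @return List: `x` (conditioned reference), `retained` (band labels),
#'   `bands` (the full [decompose_bands()] report), `rho_raw` and
#'   `rho_conditioned` (correlation with `d` before/after conditioning).
#' @export
condition_reference <- function(d, nu, cfg = wavelet_config()) {
  bd <- decompose_bands(nu, d, cfg)
  built <- build_reference(bd, cfg)
  best <- max(abs(ifelse(is.na(bd$rho), 0, bd$rho)))
  if (best < cfg$min_rho_floor) {
    warning(sprintf(
      "weak reference: best band |rho| = %.3f is below the %.2f floor",
      best, cfg$min_rho_floor))
  }
  list(x = built$x, retained = built$retained, bands = bd,
       rho_raw = pearson_cor(d, nu),
       rho_conditioned = pearson_cor(d, built$x))
}
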