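# macx — wavelet adaptive cancellation of ECG motion artifacts

`macx` removes motion artifacts from single-lead ambulatory ECG
recordings using reference signals from multiple body-worn six-axis
inertial sensors. It is aimed at people building or evaluating wearable
ECG processing chains: it ships the full method as composable R
functions, a classed canceller fit with the usual `coef()` /
`fitted()` / `residuals()` methods, a seeded synthetic-recording
generator with exact ground truth, and a small command-line driver.

## Method

The recorded ECG is modelled as `d(n) = s(n) + v(n)`: clean cardiac
signal plus a motion artifact correlated with electrode displacement.
From M six-axis inertial modules the pipeline:

1. **selects a reference**: for every module j it scores seven candidate
   channels — axes `X_j, Y_j, Z_j`, angular rates `U_j, V_j, W_j`, and
   the acceleration magnitude `R_j = sqrt(X_j² + Y_j² + Z_j²)` — by the
   Pearson correlation `ρ = cov(d, x) / (σ_d σ_x)` with the contaminated
   ECG, and keeps the channel with the largest `|ρ|` per module and then
   across modules (`ν(n)`);
2. **conditions it with wavelets**: `ν(n)` is decomposed into octave
   bands `D_1 … D_L, A_L` (undecimated transform, `sym16`, L = 10, bands
   sum additively back to `ν`); each band is correlated with `d(n)` and
   only the correlated bands are summed into the reference `x(n)`,
   discarding sensor vibration unrelated to electrode motion;
3. **cancels adaptively**: a transversal filter with tap input
   `u(n) = (x(n), …, x(n−M+1))` forms `y(n) = wᵀu(n)`,
   `e(n) = d(n) − y(n)`, updating `w ← w + 2µ e(n) u(n)` (LMS, µ = 0.03)
   or `w ← w + µ/(p + uᵀu) · e(n) u(n)` (NLMS, µ = 0.2); `e(n)` is the
   cleaned ECG;
4. **scores the result**: QRS-aligned beat segments form an M×N matrix
   X, and the eigenvalues of `D = XXᵀ` give
   `SNR = λ_max / (Σ λ − λ_max)` — the repeating cardiac complex lives
   in `λ_max`, incoherent residual noise in the rest.

Details, parameter rationale and known limitations are in the methods
vignette (`vignettes/wavelet-adaptive-cancellation.Rmd`).

## Worked example

Generate a 60 s recording whose best sensor axis is contaminated with
strong out-of-band vibration (the "decoy" scenario), run the full
pipeline, and compare the 2×2 grid {LMS, NLMS} × {raw, conditioned}:

```r
library(macx)

sim <- synth_generate_decoy(synth_config(seed = 7))
res <- run_pipeline(sim$recording, fiducials = sim$truth$beat_fiducials)
print(res)
#> <macx_run: NLMS + wavelet reference on 11997 samples @ 200 Hz>
#>   reference: left/V, rho raw 0.3477 -> conditioned 0.6343
#>   SNR: 2.0898 -> 3.0910 (delta +1.0012, 60 beats)

tab <- run_matrix(sim$recording, fiducials = sim$truth$beat_fiducials)
tab[, c("algorithm", "reference", "rho", "snr_before", "snr_after")]
#>   algorithm   reference    rho snr_before snr_after
#> 1       lms         raw 0.3477       2.09     2.241
#> 2      nlms         raw 0.3477       2.09     3.959
#> 3       lms conditioned 0.6343       2.09     3.608
#> 4      nlms conditioned 0.6343       2.09     3.091
```

Reading the numbers: the raw reference correlates with the contaminated
ECG at only |ρ| = 0.35 because decoy vibration dilutes it; wavelet band
retention nearly doubles that (0.63). The eigenvalue SNR of the cleaned
ECG rises in every cell relative to the 2.09 of the input; conditioning
clearly helps the (stability-limited, 2-tap) LMS filter, while a 32-tap
NLMS filter can null a *stationary* decoy band on its own, so its raw
cell is already strong — see the vignette for why.

The generator knows its own ground truth, so you can check cancellation
against the clean signal directly:

```r
span <- res$report$ecg_span
s <- as.numeric(sim$truth$clean_ecg)[span[1]:span[2]]
mean((as.numeric(res$cleaned) - s)^2) / mean((as.numeric(sim$truth$artifact)[span[1]:span[2]])^2)
```

## Command line

```sh
Rscript inst/cli/macx.R simulate --seed 7 --decoy --out fx/
Rscript inst/cli/macx.R run --in fx/recording.csv --report report.json --out-cleaned cleaned.csv
Rscript inst/cli/macx.R matrix --in fx/recording.csv --out table.csv
```

Verbs: `simulate`, `select`, `condition`, `cancel`, `snr`, `run`,
`matrix`. Exit codes: 0 success, 2 configuration error, 3 data error.
All stages are driven by one YAML config with blocks
`io` / `wavelet` / `filter` / `snr` / `synth`; every default is
overridable and each JSON report embeds a hash of the config that
produced it.

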