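---
title: "Wavelet adaptive cancellation of ECG motion artifacts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet adaptive cancellation of ECG motion artifacts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macx)
```

## The problem

Wearable single-lead ECG systems with dry fabric electrodes are badly
affected by motion artifacts: electrode–skin displacement injects a
large, non-stationary, broadband disturbance that can bury the P-QRS-T
morphology. Adaptive noise cancellation attacks this with a second,
*reference* channel that is correlated with the artifact but not with the
cardiac signal. Body-worn inertial sensors (accelerometer + gyroscope)
are natural reference sources — but an arbitrary axis of an arbitrary
module is usually a poor reference: the artifact appears on whichever
axes happen to couple to electrode motion, and sensor vibration that
never reaches the electrodes contaminates the channel with energy the
canceller cannot use.

`macx` implements a pipeline that addresses both problems:

1. **Reference selection.** For each of the M six-axis modules, the
   Pearson correlation between the contaminated ECG `d(n)` and each of 7
   candidate channels (axes X, Y, Z; angular rates U, V, W; acceleration
   magnitude `R = sqrt(X^2+Y^2+Z^2)`) is computed; the candidate with
   the largest `|rho|` wins per sensor, then across sensors. Because the
   winner is a maximum over a growing set, adding sensors can only help.
2. **Wavelet conditioning.** The selected channel `nu(n)` is split into
   octave bands with an undecimated wavelet transform (default `sym16`,
   10 levels); each band is correlated with `d(n)`, and only correlated
   bands are kept and summed into the conditioned reference `x(n)`. This
   strips vibration energy in bands unrelated to electrode motion.
3. **Cancellation.** An LMS or NLMS transversal filter predicts the
   artifact from `x(n)` and subtracts it: `y(n) = w'u(n)`,
   `e(n) = d(n) - y(n)`, with updates `w <- w + 2 mu e(n) u(n)` (LMS,
   the factor 2 kept explicit) or `w <- w + mu/(p + u'u) e(n) u(n)`
   (NLMS).
4. **Evaluation.** Signal quality is scored from beat-to-beat
   redundancy: QRS-aligned segments form an M x N matrix X, and
   `SNR = lambda_max / (sum(lambda) - lambda_max)` for the eigenvalues
   of `X X'`. The repeating cardiac complex concentrates in the top
   eigenvalue; incoherent noise spreads over the rest.

## Preprocessing

All channels are brought to one clock (default 200 Hz) by cubic-spline
evaluation on the target grid. When a channel is decimated, an order-8
zero-phase Butterworth low-pass at 0.45 x the target rate prevents
aliasing; the channel mean is removed before filtering and restored
afterwards so constants pass exactly. Spline interpolation has an error
that grows like `(2 pi f / rate)^4`, so content up to roughly an eighth
of the source rate is moved essentially losslessly; this is ample for
the sub-20 Hz band where motion artifacts live.

Sensors are time-aligned to the ECG by one integer-sample lag per
module, found by maximizing the absolute cross-correlation between the
module's acceleration magnitude and the ECG inside a ±2 s window (a
manual per-sensor override in seconds is available). Sub-sample delay is
left to the adaptive filter's tap line. The magnitude channel is usable
for alignment because real accelerometers measure gravity: for motion m
superimposed on the static vector g, `|g + m| ≈ |g| + m_parallel` is
linear in the motion component along gravity.

## The wavelet stage in detail

The transform is a maximal-overlap (undecimated) DWT, computed with the
standard pyramid of circular filterings with upsampled filters. Three
properties motivated this choice over a decimated DWT:

* every band is a full-length signal, so the per-band Pearson
  correlation against `d(n)` is defined sample-for-sample;
* the multiresolution analysis is *additive*: the L detail bands plus
  the smooth reconstruct the input to round-off (about 1e-11 observed)
  for any length, including lengths far too short for a decimated
  10-level transform;
* the band reconstructions are zero-phase, so retained bands stay
  aligned with the artifact.

Boundaries are handled by reflection by default: the signal is
concatenated with its time reverse, transformed circularly, and
truncated, which suppresses wrap-around artifacts while keeping the
additive identity exact. A `periodic` mode skips the extension.
Requested depths beyond `floor(log2(n))` are clamped with a warning so
short records degrade gracefully.

Two retention rules are provided. `"max"` keeps the single band with the
largest `|rho|`. The pipeline default is `"threshold"`, which keeps all
bands with `|rho| >= threshold_frac * max |rho|` (`threshold_frac`
0.5): a gross-motion artifact in the 0.5–5 Hz band spans about three
octaves, so single-band retention would discard most of the recoverable
artifact energy; multi-band retention reflects the idea of removing only
the *weakly* correlated coefficients and reconstructing from all the
strongly correlated ones. With `threshold_frac = 0` conditioning is the
identity.

Two caveats are worth knowing. Neighbouring octave bands of an
undecimated transform overlap spectrally, so conditioning is not a
projection: re-conditioning a retained band re-spreads a little energy
(the retained label is stable, but `|rho|` can dip by a few hundredths).
And the band edges roll off smoothly, so even threshold retention loses
some artifact energy near the retained bands' edges; this bounds the
achievable cancellation (see below).

## Adaptive filter parameters

* `mu` — 0.03 for LMS and 0.2 for NLMS. The LMS update keeps the
  explicit factor 2; readers comparing with the textbook convention
  without it should halve/double `mu`.
* `order` — 32 taps for NLMS (160 ms at 200 Hz, generous for an
  electrode-motion impulse response), but 2 for LMS. The asymmetry is
  forced by stability, not preference: for a unit-variance reference,
  Gaussian theory puts LMS mean-square stability at roughly
  `2 * mu * order * var(x) < 1/3` (order ≤ 5 at `mu = 0.03`), and the
  heavy-tailed error signal — the update is driven by `e(n)`, which
  contains the full R-wave spikes — erodes that margin further: orders
  8–32 diverge outright, and 4 taps still burst intermittently on a
  minority of seeds. Two taps run burst-free. NLMS's energy
  normalization removes the order dependence.
* `p` — 1e-8, the regularizer keeping the NLMS step finite on a silent
  reference.
* The pipeline standardizes the reference (zero mean, unit variance)
  before filtering: inertial units (m/s², deg/s) are arbitrary relative
  to the ECG's millivolts, and fixed step sizes are only meaningful at a
  known reference scale. `adaptive_cancel()` itself never rescales its
  inputs — the scale sensitivity of LMS versus NLMS is part of the
  algorithms' observable behaviour and is tested as such.

A divergence guard aborts with the sample index once any weight exceeds
1e8 in magnitude; this fails loudly on an unstable step instead of
returning garbage.

### A known limitation: NLMS misadjustment on narrowband references

With the printed NLMS step (`mu = 0.2`) and an artifact as strong as the
cardiac signal, steady-state gradient noise is substantial: the error
`e(n)` that drives the update contains the full (spiky) ECG, and a
narrowband conditioned reference makes it worse because its local tap
energy `u'u` periodically dips through zero, where the normalized step
`mu |e| / (p + u'u)` takes very large kicks. In this regime the
measured tail error of conditioned-NLMS sits far above the Wiener
optimum of the same reference (which is about 0.2 of the artifact
power), and no honest choice of `p` fixes it — raising `p` simply
shrinks the effective step. Consequences observed on synthetic data:
conditioned-NLMS does not reach a 0.25 residual-MSE ratio at these
settings, and on recordings with *stationary* decoy vibration an NLMS
filter fed the raw reference can match or beat the conditioned one,
since a 32-tap filter adaptively nulls a fixed decoy band on its own.
The conditioning advantage is robust for the correlation of the
reference itself and for the (short, stability-limited) LMS filter. Real
motion artifacts and vibrations are non-stationary, where a static
in-filter null is not available; the stationary generator is
conservative in this respect.

## The eigenvalue SNR

Beats are segmented as N-sample windows (default 0.6 s) centered on QRS
fiducials. The detector is a Pan–Tompkins-style chain: zero-phase 5–15 Hz
band-pass, squaring, 150 ms moving-window integration, adaptive
threshold at 0.3 x the 95th energy percentile with a 250 ms refractory
period, and refinement to the band-passed peak. On clean synthetic ECG
it finds ≥ 95% of beats within 50 ms. For synthetic data the
generator's ground-truth fiducials can be passed instead, removing
detector error from method comparisons; paired before/after estimates
always share one fiducial set.

Numerical conventions: eigenvalues of `X X'` that round off slightly
negative are clamped to zero; if the noise subspace is numerically empty
(denominator below `1e-12 * lambda_max`), the SNR is reported as `Inf`.
The eigenvalue sum equals the squared Frobenius norm of X, which the
tests verify on every call. Beat rows are used as cut — without per-row
mean removal — matching the plain definition; an optional baseline flag
was considered and rejected as an unforced extension.

## The synthetic generator

`synth_generate()` builds recordings with exact ground truth:

* **Clean ECG** — per-beat Gaussian bumps for P, Q, R, S, T (amplitudes
  0.12, −0.12, 1, −0.2, 0.35; widths 25, 10, 12, 10, 45 ms; offsets
  −200, −35, 0, 35, 250 ms) at 60 bpm with 20 ms Gaussian beat jitter.
  A dynamical-system ECG model would look prettier but adds nothing the
  assertions need; Gaussian bumps give analytic fiducials.
* **Hidden motion source** — unit-variance 0.5–5 Hz band-limited noise,
  the gross body-motion band of walking/bending-type activity.
* **Artifact** — a 3-tap FIR of the hidden source (taps 0.6, 0.3, 0.1,
  a short electrode-motion response), scaled so artifact power equals
  clean-ECG power (`artifact_gain = 1`), i.e. `MSE(d, s)/var(s) ≈ 1`.
* **Sensor channels** — per-axis mixtures
  `w_h * hidden + w_d * decoy + w_n * noise` of unit-variance
  components; the weight for a target correlation rho is
  `w = rho / sqrt(1 - rho^2)` against unit noise. The default mixing
  table plants modest correlations (0.05–0.5) everywhere and 0.9 on the
  middle module's Z axis, emulating the electrode-adjacent module; the
  accelerometer Z axes carry a 9.81 static gravity offset. Gyroscope
  channels use the same mixture machinery (the pipeline consumes them
  only through correlation, so rigid-body kinematics are not modelled).
* **Decoy scenario** — `synth_generate_decoy()` additionally loads the
  winner axis with 20–45 Hz vibration at 4 x the power of its
  artifact-correlated component. This band is disjoint (by two octaves)
  from the artifact band, which is the regime where band retention
  provably helps.

All randomness flows from one mandatory seed through fixed per-component
sub-seeds (`(seed * 7919 + k * 104729) mod (2^31 - 1)` with a distinct
`k` for jitter, hidden source, each sensor's decoy, and each axis's
noise), so changing one component's settings leaves the others' draws
untouched, and regeneration from a written `config.yaml` is
bit-identical.

What the generator does *not* emulate: non-stationary artifact
statistics, electrode pop/saturation, baseline wander, power-line
interference, rigid-body consistency between the six axes, and
subject-to-subject variability. Tests passing on this generator
demonstrate the algebraic and statistical mechanics of the method — not
clinical performance.

## Problem sizes and defaults used in tests

Records are 60 s at 200 Hz (12 000 samples, 60 beats) for the
method-level properties, shorter (8–30 s) for structural checks; system
identification uses 20 000 white-noise samples; wavelet reconstruction
is checked at lengths 4096 and 5000. The full suite and the acceptance
script each run in a few minutes on one core.

## Open design points, resolved

* **Gyroscope units** are accepted as-is (correlation is
  scale-invariant); no deg/s vs rad/s conversion is attempted.
* **Detrending before correlation** is not applied; Pearson already
  mean-centers, and an optional high-pass would only matter for slow
  non-stationarity the generator does not produce.
* **Correlation-weighted band summation** (a third reading of
  "reconstructed according to the correlation magnitude") is not
  implemented; the `max` and `threshold` rules bracket it.
* **CSV with mixed rates** stores shorter channels with empty trailing
  cells; interior gaps are parse errors — missing samples are rejected,
  never imputed, because silent imputation corrupts correlation
  estimates.
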