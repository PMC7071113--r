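Package: macx
Title: Wavelet Adaptive Cancellation of Motion Artifacts in Ambulatory ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes motion artifacts from single-lead ambulatory ECG
    recordings using inertial-sensor reference signals. Implements
    correlation-based selection of the best reference channel across
    multiple six-axis inertial sensors, wavelet multiresolution
    conditioning of the selected reference (retaining only the frequency
    bands correlated with the contaminated ECG), LMS and NLMS adaptive
    noise cancellation, and an eigenvalue-based signal-to-noise ratio
    computed from a matrix of QRS-aligned beats. Includes CSV recording
    input/output with cubic-spline resampling and cross-correlation time
    alignment, a fully seeded synthetic-recording generator with known
    ground truth, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
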