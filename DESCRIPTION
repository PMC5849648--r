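Package: cinefractal
Title: Long-Range Dependence and Spectral Slope Analysis of Film Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring fractal (1/f) temporal structure in the
    event series of feature films: shot and scene durations, per-shot motion,
    luminance, clutter, shot scale, and binned sound amplitude.  Provides a
    sliding-window Fourier power summary with a hybrid white-plus-colored
    noise model of the spectrum, the exact local Whittle estimator of the
    long-memory parameter, colored-noise and ARFIMA simulators, the
    simulation studies that calibrate both estimators (alpha-by-length
    grids, vector doubling, small-sample standard-error calibration,
    analytic power), per-shot feature operators over synthetic frame stacks
    and audio, a synthetic movie-corpus generator with controlled
    long-range dependence, and corpus-level trend statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
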