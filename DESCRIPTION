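Package: epirhythm
Title: Trend, Seasonality and Anomaly Decomposition for Multi-Site Epidemiological Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes multi-site epidemiological surveillance time series
    (weekly or monthly counts or rates) into long-term trend, harmonic
    seasonality and anomalies. Fits partial Fourier (harmonic) regressions at
    annual, semi-annual and quarterly frequencies and reports them as
    amplitude and phase; extracts comparable seasonal parameters per site
    (primary and secondary peak timing, relative amplitude); estimates
    baseline burden with user-defined exclusion windows and Student-t
    prediction intervals; quantifies excess burden above the interval;
    computes Morlet continuous wavelet power spectra; and renders geographic
    comparisons (bubble maps, latitudinal scatterplots, heat grids). Includes
    a synthetic multi-site panel generator with analytic ground truth and a
    command-line entry point for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    readxl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
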