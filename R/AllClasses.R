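#' @import methods
NULL

#' Multi-site epidemiological time-series panel
#'
#' Holds one or more observation series sharing a common calendar: a year
#' column, a within-year index (month, week, ...) in `1..P`, and one numeric
#' column per site or category. The calendar must be contiguous (every
#' `(year, subunit)` between the first and last row present exactly once) and
#' strictly ascending; observations may be missing (`NA`).
#'
#' @slot years integer, calendar year of each row.
#' @slot subunits integer, within-year index of each row (`1..periodicity`).
#' @slot periodicity integer, sub-year units per year (12 monthly, 52 weekly).
#' @slot values numeric matrix, rows = time points, columns = sites.
#' @slot siteNames character, one name per value column.
#' @slot sheetLabel character, optional third-dimension label (e.g. an age
#'   group) carried from a workbook sheet; `character(0)` when absent.
#' @export
setClass("TimeSeriesPanel",
  representation(
    years = "integer",
    subunits = "integer",
    periodicity = "integer",
    values = "matrix",
    siteNames = "character",
    sheetLabel = "character"
  )
)

setValidity("TimeSeriesPanel", function(object) {
  msg <- character(0)
  n <- length(object@years)
  P <- object@periodicity
  if (length(P) != 1L || is.na(P) || P < 1L)
    msg <- c(msg, "periodicity must be a single positive integer")
  if (length(object@subunits) != n)
    msg <- c(msg, "years and subunits must have equal length")
  if (nrow(object@values) != n)
    msg <- c(msg, "values must have one row per calendar point")
  if (ncol(object@values) != length(object@siteNames))
    msg <- c(msg, "values must have one column per site name")
  if (length(msg) == 0L && n > 0L) {
    if (any(object@subunits < 1L | object@subunits > P))
      msg <- c(msg, sprintf("subunits must lie in 1..%d", P))
    key <- object@years * as.double(P) + object@subunits
    if (any(diff(key) <= 0))
      msg <- c(msg, "rows not in ascending chronological order")
    else if (any(diff(key) != 1 & !(diff(object@years) == 1L &
        object@subunits[-n] == P & object@subunits[-1L] == 1L)))
      msg <- c(msg, "calendar has gaps")
    if (nCompleteYears(object@years, object@subunits, P) < 2L)
      msg <- c(msg, "panel must span at least 2 complete years")
  }
  if (length(msg)) msg else TRUE
})

#' Site geolocation table
#'
#' Site names with decimal-degree coordinates and an optional grouping label
#' (e.g. region or country), as read from a headerless 3- or 4-column file.
#'
#' @slot siteNames character, unique site names.
#' @slot latitudes numeric, decimal degrees in `[-90, 90]`.
#' @slot longitudes numeric, decimal degrees in `[-180, 180]`.
#' @slot groups character, optional group labels (`character(0)` when absent).
#' @export
setClass("GeoTable",
  representation(
    siteNames = "character",
    latitudes = "numeric",
    longitudes = "numeric",
    groups = "character"
  )
)

setValidity("GeoTable", function(object) {
  msg <- character(0)
  n <- length(object@siteNames)
  if (anyDuplicated(object@siteNames))
    msg <- c(msg, "duplicate site names")
  if (length(object@latitudes) != n || length(object@longitudes) != n)
    msg <- c(msg, "coordinate vectors must match site names in length")
  if (any(abs(object@latitudes) > 90, na.rm = TRUE))
    msg <- c(msg, "latitude out of range [-90, 90]")
  if (any(abs(object@longitudes) > 180, na.rm = TRUE))
    msg <- c(msg, "longitude out of range [-180, 180]")
  if (length(object@groups) && length(object@groups) != n)
    msg <- c(msg, "groups, when present, must match site names in length")
  if (length(msg)) msg else TRUE
})

#' Validation report for an input table
#'
#' @slot ok logical, `TRUE` iff no issue has severity `"error"`.
#' @slot issues data.frame with columns `severity`, `locus`, `message`.
#' @export
setClass("ValidationReport",
  representation(ok = "logical", issues = "data.frame")
)

setValidity("ValidationReport", function(object) {
  want <- !any(object@issues$severity == "error")
  if (identical(object@ok, want)) TRUE
  else "ok must be TRUE exactly when no issue has severity 'error'"
})

#' Long-term trend model
#'
#' Polynomial (default cubic) or penalised cubic smoothing-spline trend over
#' fractional-year time, fitted by least squares to the non-missing
#' observations and evaluated on the full calendar. Polynomial coefficients
#' are in ascending-power order over centred time `t - timeOrigin`.
#'
#' @slot method `"polynomial"` or `"spline"`.
#' @slot order integer polynomial order (`integer(0)` for splines).
#' @slot coefficients ascending-power coefficients (polynomial only).
#' @slot stiffness smoothing weight actually used (spline only).
#' @slot fitted trend evaluated at every calendar point (no missing values).
#' @slot time fractional-year axis the model is aligned with.
#' @slot timeOrigin centre of the time axis used for conditioning.
#' @export
setClass("TrendModel",
  representation(
    method = "character",
    order = "integer",
    coefficients = "numeric",
    stiffness = "numeric",
    fitted = "numeric",
    time = "numeric",
    timeOrigin = "numeric"
  )
)

setValidity("TrendModel", function(object) {
  msg <- character(0)
  if (!object@method %in% c("polynomial", "spline"))
    msg <- c(msg, "method must be 'polynomial' or 'spline'")
  if (length(object@fitted) != length(object@time))
    msg <- c(msg, "fitted and time must have equal length")
  if (anyNA(object@fitted))
    msg <- c(msg, "fitted values must be defined on the whole calendar")
  if (object@method == "polynomial" &&
      length(object@coefficients) != object@order + 1L)
    msg <- c(msg, "polynomial coefficients must have length order + 1")
  if (length(msg)) msg else TRUE
})

#' Harmonic (partial Fourier) seasonal model
#'
#' A mean level plus sinusoids at the configured frequencies (cycles per
#' year; 1, 2 and 4 by default, i.e. 12-, 6- and 3-month cycles), each
#' reported as amplitude and phase so that component `k` equals
#' `A_k * cos(2*pi*k*t - phi_k)` with `t` in fractional years.
#'
#' @slot meanLevel mean level in series units.
#' @slot frequencies cycles per year, distinct.
#' @slot amplitudes non-negative amplitudes `A_k`.
#' @slot phases phases `phi_k` in `[0, 2*pi)`.
#' @slot periodicity sub-year units per year of the fitted series.
#' @export
setClass("HarmonicModel",
  representation(
    meanLevel = "numeric",
    frequencies = "numeric",
    amplitudes = "numeric",
    phases = "numeric",
    periodicity = "integer"
  )
)

setValidity("HarmonicModel", function(object) {
  msg <- character(0)
  k <- length(object@frequencies)
  if (length(object@amplitudes) != k || length(object@phases) != k)
    msg <- c(msg, "frequencies, amplitudes and phases must align")
  if (anyDuplicated(object@frequencies))
    msg <- c(msg, "harmonic frequencies must be distinct")
  if (any(object@amplitudes < 0))
    msg <- c(msg, "amplitudes must be non-negative")
  if (any(object@phases < 0 | object@phases >= 2 * pi))
    msg <- c(msg, "phases must lie in [0, 2*pi)")
  if (length(msg)) msg else TRUE
})

#' Average within-year seasonal signature
#'
#' The harmonic model evaluated on a uniform grid of within-year positions
#' `u` in `[0, 1)`; year-to-year variation is removed by construction. The
#' generating model is retained so peak search can refine beyond the grid.
#'
#' @slot grid within-year positions in `[0, 1)`.
#' @slot values signature values on the grid.
#' @slot model the generating [HarmonicModel-class].
#' @export
setClass("SeasonalSignature",
  representation(grid = "numeric", values = "numeric", model = "HarmonicModel")
)

setValidity("SeasonalSignature", function(object) {
  if (length(object@grid) != length(object@values))
    "grid and values must have equal length"
  else TRUE
})

#' Seasonal peak parameters
#'
#' Primary peak and trough of the seasonal signature (times in months,
#' `[0, 12)`), the relative amplitude `(peak - trough) / peak`, and an
#' optional secondary peak for bimodal signatures.
#'
#' @slot peakTime,peakValue primary peak (global maximum).
#' @slot troughTime,troughValue primary trough (global minimum).
#' @slot amplitude relative amplitude of the primary peak (`NA` when
#'   undefined, i.e. non-positive peak value or degenerate signature).
#' @slot amplitudeFlag `"ok"`, `"undefined"` (peak <= 0), `"exceeds_one"`
#'   (negative trough), or `"degenerate"` (flat signature).
#' @slot secondaryTime,secondaryValue,secondaryAmplitude secondary peak
#'   fields; `numeric(0)` when no qualifying secondary peak exists.
#' @slot degenerate logical, `TRUE` for an (effectively) constant signature.
#' @export
setClass("PeakSet",
  representation(
    peakTime = "numeric", peakValue = "numeric",
    troughTime = "numeric", troughValue = "numeric",
    amplitude = "numeric", amplitudeFlag = "character",
    secondaryTime = "numeric", secondaryValue = "numeric",
    secondaryAmplitude = "numeric",
    degenerate = "logical"
  )
)

#' Baseline burden model with exclusions and prediction intervals
#'
#' Joint least-squares fit of a polynomial trend and harmonic seasonality to
#' the non-excluded, non-missing observations, evaluated over the full
#' calendar. Supports Student-t prediction intervals for new observations at
#' the configured level; observations outside the interval are anomalies.
#'
#' @slot trend the [TrendModel-class] component.
#' @slot harmonics the [HarmonicModel-class] component (mean level 0; the
#'   intercept lives in the trend).
#' @slot baseline fitted baseline on the full calendar.
#' @slot residualScale standard deviation of in-sample residuals over the
#'   non-excluded, non-missing points (denominator `nFit - nParams`).
#' @slot nFit number of observations used in the fit.
#' @slot nParams number of fitted regression parameters.
#' @slot level two-sided interval level in (0, 1), default 0.95.
#' @slot mask logical exclusion mask aligned with the calendar.
#' @slot time fractional-year calendar axis.
#' @export
setClass("BaselineModel",
  representation(
    trend = "TrendModel",
    harmonics = "HarmonicModel",
    baseline = "numeric",
    residualScale = "numeric",
    nFit = "integer",
    nParams = "integer",
    level = "numeric",
    mask = "logical",
    time = "numeric"
  )
)

setValidity("BaselineModel", function(object) {
  msg <- character(0)
  if (object@residualScale < 0) msg <- c(msg, "residualScale must be >= 0")
  if (object@nFit < object@nParams + 2L)
    msg <- c(msg, "nFit must be at least nParams + 2")
  if (object@level <= 0 || object@level >= 1)
    msg <- c(msg, "level must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Catalogue of observations outside the prediction interval
#'
#' One row per non-missing observation strictly outside its interval bound:
#' calendar point, observed and baseline values, bounds, direction
#' (`"above"`/`"below"`) and signed magnitude (observed minus the violated
#' bound; positive above, negative below).
#'
#' @slot catalogue data.frame with columns `year`, `subunit`, `index`,
#'   `observed`, `baseline`, `lower`, `upper`, `direction`, `magnitude`.
#' @export
setClass("AnomalyCatalogue", representation(catalogue = "data.frame"))

setValidity("AnomalyCatalogue", function(object) {
  df <- object@catalogue
  msg <- character(0)
  if (nrow(df)) {
    up <- df$direction == "above"
    if (any(up & !(df$observed > df$upper)) ||
        any(!up & !(df$observed < df$lower)))
      msg <- c(msg, "every entry must strictly violate its bound")
    if (any(df$magnitude[up] <= 0) || any(df$magnitude[!up] >= 0))
      msg <- c(msg, "magnitudes must be positive above and negative below")
  }
  if (length(msg)) msg else TRUE
})

#' Morlet continuous wavelet transform result
#'
#' Wavelet power (variance units) per scale and time point, the Fourier
#' period of each scale, and the cone of influence giving the longest
#' trustworthy period at each time point.
#'
#' @slot power scales-by-time matrix of `|W|^2`.
#' @slot periods Fourier period per scale, strictly increasing.
#' @slot scales wavelet scales.
#' @slot coi cone of influence per time point (same period units).
#' @slot time time axis of the input series.
#' @slot params list: `dt`, `s0`, `dj`, `J`, `omega0` (Morlet, fixed 6).
#' @export
setClass("WaveletResult",
  representation(
    power = "matrix", periods = "numeric", scales = "numeric",
    coi = "numeric", time = "numeric", params = "list"
  )
)

setValidity("WaveletResult", function(object) {
  msg <- character(0)
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (any(diff(object@periods) <= 0))
    msg <- c(msg, "periods must be strictly increasing")
  if (ncol(object@power) != length(object@coi))
    msg <- c(msg, "coi must have one value per time point")
  if (length(msg)) msg else TRUE
})

#' Per-site extracted parameter table
#'
#' One row per geo-matched site holding the exported analysis parameters:
#' coordinates and group, mean level, linear trend coefficient, amplitude and
#' phase per harmonic, primary peak time and relative amplitude (with flag),
#' optional secondary peak fields, optional total excess and anomaly counts.
#' The column set is stable regardless of which optional analyses ran.
#'
#' @slot table the parameter data.frame (one row per site).
#' @export
setClass("SiteParameterTable", representation(table = "data.frame"))

setValidity("SiteParameterTable", function(object) {
  df <- object@table
  msg <- character(0)
  if (nrow(df)) {
    pt <- df$peak_time[!is.na(df$peak_time)]
    if (any(pt < 0 | pt >= 12)) msg <- c(msg, "peak times must lie in [0, 12)")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic panel configuration
#'
#' Ground-truth recipe for [generatePanel()]: per-site trend polynomial,
#' harmonic amplitudes/phases (or a latitude-to-peak-month linear rule),
#' Gaussian noise, injected epidemic/pandemic burdens and missingness, with a
#' mandatory seed for bit-identical reproduction.
#'
#' @slot config named list of generator settings (see [synthConfig()]).
#' @export
setClass("SynthConfig", representation(config = "list"))
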