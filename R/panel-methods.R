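#' Construct a TimeSeriesPanel
#'
#' @param years,subunits integer calendar columns (year; within-year index).
#' @param values numeric matrix or data.frame, one column per site.
#' @param periodicity sub-year units per year; inferred as `max(subunits)`
#'   when `NULL`.
#' @param siteNames site names; defaults to the column names of `values`.
#' @param sheetLabel optional third-dimension label.
#' @return a validated [TimeSeriesPanel-class].
#' @examples
#' p <- TimeSeriesPanel(rep(2001:2002, each = 12), rep(1:12, 2),
#'                      matrix(rnorm(24), ncol = 1, dimnames = list(NULL, "A")))
#' periodicity(p)
#' @export
TimeSeriesPanel <- function(years, subunits, values, periodicity = NULL,
                            siteNames = colnames(values),
                            sheetLabel = character(0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(siteNames))
    siteNames <- paste0("S", seq_len(ncol(values)))
  if (is.null(periodicity)) periodicity <- max(subunits)
  colnames(values) <- siteNames
  new("TimeSeriesPanel",
      years = as.integer(years), subunits = as.integer(subunits),
      periodicity = as.integer(periodicity), values = values,
      siteNames = as.character(siteNames),
      sheetLabel = as.character(sheetLabel))
}

#' @rdname TimeSeriesPanel-class
#' @export
setMethod("siteNames", "TimeSeriesPanel", function(x) x@siteNames)

#' @rdname TimeSeriesPanel-class
#' @export
setMethod("periodicity", "TimeSeriesPanel", function(x) x@periodicity)

#' @rdname TimeSeriesPanel-class
#' @export
setMethod("panelYears", "TimeSeriesPanel", function(x) x@years)

#' @rdname TimeSeriesPanel-class
#' @export
setMethod("panelSubunits", "TimeSeriesPanel", function(x) x@subunits)

#' @rdname TimeSeriesPanel-class
#' @export
setMethod("panelValues", "TimeSeriesPanel", function(x) x@values)

#' @rdname TimeSeriesPanel-class
#' @export
setMethod("fracYears", "TimeSeriesPanel",
  function(x) fracYearAxis(x@years, x@subunits, x@periodicity))

setMethod("show", "TimeSeriesPanel", function(object) {
  n <- length(object@years)
  cat(sprintf(
    "TimeSeriesPanel: %d sites x %d time points (P = %d), %d-%02d to %d-%02d\n",
    ncol(object@values), n, object@periodicity,
    object@years[1], object@subunits[1],
    object@years[n], object@subunits[n]))
  if (length(object@sheetLabel))
    cat("  sheet:", object@sheetLabel, "\n")
  miss <- sum(is.na(object@values))
  cat(sprintf("  sites: %s\n  missing values: %d\n",
              paste(utils::head(object@siteNames, 6), collapse = ", "), miss))
})

#' Construct a GeoTable
#'
#' @param siteNames,latitudes,longitudes site coordinates (decimal degrees).
#' @param groups optional grouping labels (region, country, ...).
#' @return a validated [GeoTable-class].
#' @export
GeoTable <- function(siteNames, latitudes, longitudes, groups = character(0)) {
  new("GeoTable", siteNames = as.character(siteNames),
      latitudes = as.numeric(latitudes), longitudes = as.numeric(longitudes),
      groups = as.character(groups))
}

#' @rdname GeoTable-class
#' @export
setMethod("siteNames", "GeoTable", function(x) x@siteNames)

setMethod("show", "GeoTable", function(object) {
  cat(sprintf("GeoTable: %d sites%s\n", length(object@siteNames),
              if (length(object@groups)) sprintf(" in %d groups",
                length(unique(object@groups))) else ""))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %s (%d issues)\n",
              if (object@ok) "ok" else "NOT ok", nrow(object@issues)))
  if (nrow(object@issues))
    print(object@issues, row.names = FALSE)
})

#' @rdname HarmonicModel-class
#' @export
setMethod("amplitudes", "HarmonicModel", function(x) x@amplitudes)

#' @rdname HarmonicModel-class
#' @export
setMethod("phases", "HarmonicModel", function(x) x@phases)

#' @rdname HarmonicModel-class
#' @export
setMethod("harmonicFrequencies", "HarmonicModel", function(x) x@frequencies)

setMethod("show", "HarmonicModel", function(object) {
  cat("HarmonicModel: mean level", format(object@meanLevel, digits = 4), "\n")
  for (i in seq_along(object@frequencies))
    cat(sprintf("  k = %g cycles/yr: A = %.4g, phi = %.4g rad\n",
                object@frequencies[i], object@amplitudes[i], object@phases[i]))
})

#' @rdname TrendModel-class
#' @export
setMethod("trendFitted", "TrendModel", function(x) x@fitted)

setMethod("show", "TrendModel", function(object) {
  if (object@method == "polynomial")
    cat(sprintf("TrendModel: polynomial order %d over centred time (origin %.2f)\n",
                object@order, object@timeOrigin))
  else
    cat(sprintf("TrendModel: cubic smoothing spline (stiffness %.4g)\n",
                object@stiffness))
})

setMethod("show", "PeakSet", function(object) {
  if (object@degenerate) {
    cat("PeakSet: degenerate (flat signature), amplitude 0\n")
    return(invisible(NULL))
  }
  cat(sprintf("PeakSet: peak %.2f mo (%.4g), trough %.2f mo (%.4g), amplitude %s [%s]\n",
              object@peakTime, object@peakValue, object@troughTime,
              object@troughValue,
              if (is.na(object@amplitude)) "NA"
              else format(object@amplitude, digits = 4),
              object@amplitudeFlag))
  if (length(object@secondaryTime))
    cat(sprintf("  secondary peak %.2f mo (%.4g), amplitude %.4g\n",
                object@secondaryTime, object@secondaryValue,
                object@secondaryAmplitude))
})

#' @rdname BaselineModel-class
#' @export
setMethod("residualScale", "BaselineModel", function(x) x@residualScale)

#' @rdname BaselineModel-class
#' @export
setMethod("baselineValues", "BaselineModel", function(x) x@baseline)

setMethod("show", "BaselineModel", function(object) {
  cat(sprintf(
    "BaselineModel: trend order %d + %d harmonics; n = %d, p = %d, s = %.4g, level %.2f\n",
    object@trend@order, length(object@harmonics@frequencies),
    object@nFit, object@nParams, object@residualScale, object@level))
  if (any(object@mask))
    cat(sprintf("  excluded points: %d\n", sum(object@mask)))
})

#' @rdname AnomalyCatalogue-class
#' @param x an `AnomalyCatalogue`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "AnomalyCatalogue", function(x, ...) x@catalogue)

setMethod("show", "AnomalyCatalogue", function(object) {
  df <- object@catalogue
  cat(sprintf("AnomalyCatalogue: %d anomalies (%d above, %d below)\n",
              nrow(df), sum(df$direction == "above"),
              sum(df$direction == "below")))
})

#' @rdname WaveletResult-class
#' @export
setMethod("wavePower", "WaveletResult", function(x) x@power)

#' @rdname WaveletResult-class
#' @export
setMethod("wavePeriods", "WaveletResult", function(x) x@periods)

setMethod("show", "WaveletResult", function(object) {
  cat(sprintf(
    "WaveletResult: Morlet (omega0 = %g), %d scales x %d time points, periods %.3g-%.3g\n",
    object@params$omega0, nrow(object@power), ncol(object@power),
    min(object@periods), max(object@periods)))
})

#' @rdname SiteParameterTable-class
#' @param x a `SiteParameterTable`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "SiteParameterTable", function(x, ...) x@table)

setMethod("show", "SiteParameterTable", function(object) {
  cat(sprintf("SiteParameterTable: %d sites x %d parameters\n",
              nrow(object@table), ncol(object@table) - 1L))
})

setMethod("show", "SynthConfig", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SynthConfig: %d sites, %d years (P = %d), noise %s, %d injections, seed %d\n",
    cfg$nSites, cfg$years, cfg$periodicity,
    if (cfg$noiseType == "fraction") sprintf("%.1f%% of mean", 100 * cfg$noiseSd)
    else sprintf("sd %.3g", cfg$noiseSd),
    length(cfg$pandemics), cfg$seed))
})
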