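#' @rdname TimeSeriesPanel-class
#' @param x,object an object.
#' @export
setGeneric("siteNames", function(x) standardGeneric("siteNames"))

#' @rdname TimeSeriesPanel-class
#' @export
setGeneric("periodicity", function(x) standardGeneric("periodicity"))

#' @rdname TimeSeriesPanel-class
#' @export
setGeneric("panelYears", function(x) standardGeneric("panelYears"))

#' @rdname TimeSeriesPanel-class
#' @export
setGeneric("panelSubunits", function(x) standardGeneric("panelSubunits"))

#' @rdname TimeSeriesPanel-class
#' @export
setGeneric("panelValues", function(x) standardGeneric("panelValues"))

#' @rdname TimeSeriesPanel-class
#' @export
setGeneric("fracYears", function(x) standardGeneric("fracYears"))

#' @rdname HarmonicModel-class
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' @rdname HarmonicModel-class
#' @export
setGeneric("phases", function(x) standardGeneric("phases"))

#' @rdname HarmonicModel-class
#' @export
setGeneric("harmonicFrequencies", function(x) standardGeneric("harmonicFrequencies"))

#' @rdname TrendModel-class
#' @export
setGeneric("trendFitted", function(x) standardGeneric("trendFitted"))

#' @rdname BaselineModel-class
#' @export
setGeneric("residualScale", function(x) standardGeneric("residualScale"))

#' @rdname BaselineModel-class
#' @export
setGeneric("baselineValues", function(x) standardGeneric("baselineValues"))

#' Prediction interval of a baseline model
#'
#' Lower and upper bounds `baseline -/+ q * residualScale`, where `q` is the
#' two-sided Student-t quantile at the model's level with `nFit - nParams`
#' degrees of freedom.
#'
#' @param model a fitted [BaselineModel-class].
#' @param level optional level overriding the model's own.
#' @return list with numeric vectors `lower` and `upper` on the full calendar.
#' @export
setGeneric("predictionInterval",
  function(model, level = NULL) standardGeneric("predictionInterval"))

#' @rdname WaveletResult-class
#' @export
setGeneric("wavePower", function(x) standardGeneric("wavePower"))

#' @rdname WaveletResult-class
#' @export
setGeneric("wavePeriods", function(x) standardGeneric("wavePeriods"))

#' Time-averaged wavelet power inside the cone of influence
#'
#' @param result a [WaveletResult-class].
#' @return numeric vector, one mean power per scale, averaged over the time
#'   points whose cone of influence covers that scale's period; `NA` for
#'   scales never inside the cone.
#' @export
setGeneric("globalSpectrum", function(result) standardGeneric("globalSpectrum"))
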