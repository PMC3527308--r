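# Baseline modelling with exclusion windows. To estimate excess burden
# attributable to an unusual event (e.g. a pandemic year), the event period
# is first excluded from the fit — otherwise the unusually high burden
# biases the baseline itself — and burden above the prediction interval over
# the event window is the excess.

#' Build an exclusion mask over the panel calendar
#'
#' @param years,subunits calendar columns.
#' @param P sub-year units per year.
#' @param windows periods to exclude from fitting: a numeric vector of whole
#'   calendar years, or a list of inclusive
#'   `c(startYear, startSubunit, endYear, endSubunit)` spans. `NULL` or
#'   empty excludes nothing.
#' @return logical vector, `TRUE` exactly on the listed points. At least two
#'   complete years must remain un-excluded.
#' @examples
#' yr <- rep(2000:2010, each = 12); mo <- rep(1:12, 11)
#' sum(exclusionMask(yr, mo, 12, windows = c(2009, 2010)))  # 24
#' @export
exclusionMask <- function(years, subunits, P, windows = NULL) {
  mask <- rep(FALSE, length(years))
  mask[windowIndices(years, subunits, P, windows)] <- TRUE
  if (nCompleteYearsUnmasked(years, subunits, P, mask) < 2L)
    stop("fewer than 2 complete years remain after exclusion")
  mask
}

#' Fit a baseline burden model with exclusions
#'
#' Jointly fits a polynomial trend and harmonic seasonality by ordinary
#' least squares to the non-excluded, non-missing observations only, then
#' evaluates the baseline over the full calendar (including the excluded
#' spans). The residual scale is the standard deviation of the in-sample
#' residuals at the fit points, with denominator `nFit - nParams`.
#'
#' @param x numeric observations.
#' @param years,subunits calendar columns aligned with `x`.
#' @param P sub-year units per year.
#' @param mask logical exclusion mask (see [exclusionMask()]); `NULL` for
#'   no exclusions.
#' @param trendOrder polynomial trend order (default cubic).
#' @param frequencies harmonic frequencies in cycles/year (default
#'   `c(1, 2, 4)`).
#' @param level two-sided prediction-interval level (default 0.95).
#' @return a [BaselineModel-class].
#' @export
fitBaseline <- function(x, years, subunits, P = max(subunits), mask = NULL,
                        trendOrder = 3L, frequencies = c(1, 2, 4),
                        level = 0.95) {
  n <- length(x)
  t <- fracYearAxis(years, subunits, P)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (length(mask) != n) stop("mask length must match the series")
  if (anyDuplicated(frequencies)) stop("duplicate harmonic frequencies")
  t0 <- mean(range(t))
  K <- length(frequencies)
  X <- cbind(outer(t - t0, 0:trendOrder, `^`),
             do.call(cbind, lapply(frequencies, function(k)
               cbind(cos(2 * pi * k * t), sin(2 * pi * k * t)))))
  p <- ncol(X)
  fitIdx <- which(!mask & !is.na(x))
  if (length(fitIdx) < p + 2L)
    stop(sprintf("need at least %d non-excluded, non-missing points, have %d",
                 p + 2L, length(fitIdx)))
  fit <- stats::lm.fit(X[fitIdx, , drop = FALSE], x[fitIdx])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  baseline <- as.numeric(X %*% beta)
  rss <- sum((x[fitIdx] - baseline[fitIdx])^2)
  s <- sqrt(rss / (length(fitIdx) - p))

  trendCoef <- unname(beta[seq_len(trendOrder + 1L)])
  trend <- new("TrendModel", method = "polynomial",
               order = as.integer(trendOrder), coefficients = trendCoef,
               stiffness = numeric(0),
               fitted = as.numeric(outer(t - t0, 0:trendOrder, `^`) %*% trendCoef),
               time = t, timeOrigin = t0)
  a <- beta[trendOrder + 1L + seq(1L, by = 2L, length.out = K)]
  b <- beta[trendOrder + 1L + seq(2L, by = 2L, length.out = K)]
  A <- sqrt(a^2 + b^2)
  harm <- new("HarmonicModel", meanLevel = 0,
              frequencies = as.numeric(frequencies), amplitudes = unname(A),
              phases = unname(.wrapPhase(ifelse(A > 0, atan2(b, a), 0))),
              periodicity = as.integer(P))
  new("BaselineModel", trend = trend, harmonics = harm, baseline = baseline,
      residualScale = s, nFit = length(fitIdx), nParams = as.integer(p),
      level = level, mask = mask, time = t)
}

#' @rdname predictionInterval
#' @export
setMethod("predictionInterval", "BaselineModel", function(model, level = NULL) {
  if (is.null(level)) level <- model@level
  q <- stats::qt(1 - (1 - level) / 2, df = model@nFit - model@nParams)
  half <- q * model@residualScale
  list(lower = model@baseline - half, upper = model@baseline + half)
})

#' Catalogue observations outside the prediction interval
#'
#' Every non-missing observation strictly above the upper bound or strictly
#' below the lower bound is catalogued with its calendar point, direction
#' and magnitude (observed minus the violated bound). Points exactly on a
#' bound are not anomalies. Reporting can be restricted to the excluded
#' periods or to any window.
#'
#' @param x numeric observations.
#' @param model a fitted [BaselineModel-class].
#' @param years,subunits calendar columns aligned with `x`.
#' @param restrictTo optional restriction: `"excluded"` (the model's
#'   exclusion mask), a logical mask, or windows as in [exclusionMask()].
#' @return an [AnomalyCatalogue-class].
#' @export
detectAnomalies <- function(x, model, years, subunits, restrictTo = NULL) {
  bounds <- predictionInterval(model)
  P <- model@harmonics@periodicity
  keep <- rep(TRUE, length(x))
  if (!is.null(restrictTo)) {
    if (identical(restrictTo, "excluded")) keep <- model@mask
    else if (is.logical(restrictTo)) keep <- restrictTo
    else keep <- seq_along(x) %in% windowIndices(years, subunits, P, restrictTo)
  }
  above <- which(keep & !is.na(x) & x > bounds$upper)
  below <- which(keep & !is.na(x) & x < bounds$lower)
  idx <- c(above, below)
  ord <- order(idx)
  df <- data.frame(
    year = years[idx], subunit = subunits[idx], index = idx,
    observed = x[idx], baseline = model@baseline[idx],
    lower = bounds$lower[idx], upper = bounds$upper[idx],
    direction = rep(c("above", "below"), c(length(above), length(below))),
    magnitude = c(x[above] - bounds$upper[above],
                  x[below] - bounds$lower[below]),
    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(df) <- NULL
  new("AnomalyCatalogue", catalogue = df)
}

#' Excess burden over a window
#'
#' Default (`reference = "upper_bound"`): the sum of observations above the
#' prediction interval's upper bound over the window,
#' `sum(max(observed - upper, 0))` — burden beyond expected variability.
#' The alternative `reference = "baseline"` sums the signed differences
#' `observed - baseline` over the window; it is the convention of much of
#' the excess-mortality literature but is not the default here.
#'
#' @param x numeric observations.
#' @param model a fitted [BaselineModel-class].
#' @param years,subunits calendar columns aligned with `x`.
#' @param window the event window: whole years or spans as in
#'   [exclusionMask()]; must select at least one point.
#' @param reference `"upper_bound"` (default) or `"baseline"`.
#' @return list: `total` (the excess), `contributions` (per-point values
#'   over the full calendar, zero/irrelevant outside the window), `index`
#'   (the window's row indices).
#' @export
excessBurden <- function(x, model, years, subunits, window,
                         reference = c("upper_bound", "baseline")) {
  reference <- match.arg(reference)
  P <- model@harmonics@periodicity
  idx <- windowIndices(years, subunits, P, window)
  if (!length(idx)) stop("window selects no calendar points")
  contrib <- numeric(length(x))
  if (reference == "upper_bound") {
    upper <- predictionInterval(model)$upper
    contrib[idx] <- pmax(x[idx] - upper[idx], 0)
  } else {
    contrib[idx] <- x[idx] - model@baseline[idx]
  }
  contrib[is.na(contrib)] <- 0
  list(total = sum(contrib[idx]), contributions = contrib, index = idx)
}
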