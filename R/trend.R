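# Long-term trend estimation. All fitting happens on fractional-year time
# centred at the series midpoint: with calendar years in the thousands an
# uncentred cubic design matrix is catastrophically ill-conditioned.

#' Fit a polynomial trend
#'
#' Ordinary least squares of the observations on powers `0..order` of
#' centred fractional-year time. Missing observations are excluded from the
#' fit; the trend is evaluated on the full calendar, so `trendFitted()`
#' contains no missing values.
#'
#' @param x numeric observations (missing allowed).
#' @param t fractional-year time axis (see [fracYears()]), same length.
#' @param order polynomial order, default cubic (3).
#' @return a [TrendModel-class] with ascending-power `coefficients` over
#'   `t - timeOrigin`.
#' @examples
#' t <- 2000 + (seq_len(120) - 0.5) / 12
#' x <- 5 + 0.3 * (t - 2005)
#' fitPolynomialTrend(x, t, order = 1)
#' @export
fitPolynomialTrend <- function(x, t, order = 3L) {
  if (length(x) != length(t)) stop("x and t must have equal length")
  if (order < 0) stop("polynomial order must be >= 0")
  obs <- which(!is.na(x))
  if (length(obs) < order + 2L)
    stop(sprintf("need at least %d non-missing points for order %d, have %d",
                 order + 2L, order, length(obs)))
  t0 <- mean(range(t))
  X <- outer(t - t0, 0:order, `^`)
  fit <- stats::lm.fit(X[obs, , drop = FALSE], x[obs])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  new("TrendModel", method = "polynomial", order = as.integer(order),
      coefficients = unname(beta), stiffness = numeric(0),
      fitted = as.numeric(X %*% beta), time = t, timeOrigin = t0)
}

#' Linear trend coefficient in series units per year
#'
#' The slope of a first-order polynomial trend: a single comparable number
#' per site (e.g. long-term change in mortality per year) suitable for
#' geographic comparison.
#'
#' @inheritParams fitPolynomialTrend
#' @return slope in series units per calendar year.
#' @export
linearTrendCoefficient <- function(x, t) {
  if (sum(!is.na(x)) < 3L) stop("need at least 3 non-missing points")
  fitPolynomialTrend(x, t, order = 1L)@coefficients[2L]
}

#' Fit a cubic smoothing-spline trend
#'
#' Penalised natural cubic smoothing spline over fractional-year time
#' (Reinsch algorithm, roughness penalty `stiffness * integral(f'')^2` with
#' time in years): a flexible detrending option for series whose long-term
#' pattern is not polynomial. As `stiffness` grows the fit approaches the
#' least-squares straight line (the penalty's null space); as it shrinks the
#' fit approaches interpolation of the non-missing points.
#' `stiffness = 0` is rejected — exact interpolation would remove all signal
#' and is not detrending.
#'
#' @inheritParams fitPolynomialTrend
#' @param stiffness positive smoothing weight; when `NULL`, chosen so the
#'   effective degrees of freedom are about one per five years of data.
#' @return a [TrendModel-class]; the `stiffness` slot records the weight
#'   actually used.
#' @export
fitSplineTrend <- function(x, t, stiffness = NULL) {
  if (length(x) != length(t)) stop("x and t must have equal length")
  obs <- which(!is.na(x))
  if (length(obs) < 8L) stop("need at least 8 non-missing points")
  if (!is.null(stiffness) && stiffness <= 0)
    stop("stiffness must be strictly positive")
  tx <- t[obs]; y <- x[obs]
  if (is.null(stiffness)) {
    targetDf <- max(3, ceiling(diff(range(t)) / 5) + 1)
    # effective df is monotone decreasing in log-stiffness, from n to 2
    f <- function(loglam) .reinschDf(tx, 10^loglam) - targetDf
    stiffness <- 10^stats::uniroot(f, c(-10, 10), tol = 0.01)$root
  }
  fit <- .reinschSpline(tx, y, stiffness)
  new("TrendModel", method = "spline", order = integer(0),
      coefficients = numeric(0), stiffness = stiffness,
      fitted = .evalNaturalSpline(tx, fit$fitted, fit$M, t),
      time = t, timeOrigin = mean(range(t)))
}

# Reinsch smoothing spline: minimises ||y - f||^2 + lambda * f' K f with
# K = Q R^-1 Q', solved as (R + lambda Q'Q) gamma = Q'y, f = y - lambda Q gamma;
# gamma are the spline's interior second derivatives (natural ends = 0)
.reinschBands <- function(tx) {
  n <- length(tx)
  h <- diff(tx)
  Q <- matrix(0, n, n - 2L)
  R <- matrix(0, n - 2L, n - 2L)
  for (j in seq_len(n - 2L)) {
    Q[j, j] <- 1 / h[j]
    Q[j + 1L, j] <- -(1 / h[j] + 1 / h[j + 1L])
    Q[j + 2L, j] <- 1 / h[j + 1L]
    R[j, j] <- (h[j] + h[j + 1L]) / 3
    if (j < n - 2L) R[j, j + 1L] <- R[j + 1L, j] <- h[j + 1L] / 6
  }
  list(Q = Q, R = R)
}

.reinschSpline <- function(tx, y, lambda) {
  b <- .reinschBands(tx)
  A <- b$R + lambda * crossprod(b$Q)
  gamma <- solve(A, crossprod(b$Q, y))
  list(fitted = as.numeric(y - lambda * b$Q %*% gamma),
       M = c(0, as.numeric(gamma), 0))
}

.reinschDf <- function(tx, lambda) {
  b <- .reinschBands(tx)
  A <- b$R + lambda * crossprod(b$Q)
  # df = tr(I - lambda Q A^-1 Q') = n - lambda tr(A^-1 Q'Q)
  length(tx) - lambda * sum(diag(solve(A, crossprod(b$Q))))
}

# evaluate a natural cubic spline (knots tx, values f, second derivatives M)
# at xout; linear extrapolation beyond the knot range
.evalNaturalSpline <- function(tx, f, M, xout) {
  n <- length(tx)
  h <- diff(tx)
  i <- findInterval(xout, tx, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n - 1L)
  lo <- tx[i]; hi <- tx[i + 1L]; hh <- h[i]
  a <- (hi - xout) / hh; bfrac <- (xout - lo) / hh
  val <- a * f[i] + bfrac * f[i + 1L] +
    ((a^3 - a) * M[i] + (bfrac^3 - bfrac) * M[i + 1L]) * hh^2 / 6
  # natural-spline linear extrapolation outside the knots
  left <- xout < tx[1L]
  if (any(left)) {
    s <- (f[2L] - f[1L]) / h[1L] - h[1L] * M[2L] / 6
    val[left] <- f[1L] + s * (xout[left] - tx[1L])
  }
  right <- xout > tx[n]
  if (any(right)) {
    s <- (f[n] - f[n - 1L]) / h[n - 1L] + h[n - 1L] * M[n - 1L] / 6
    val[right] <- f[n] + s * (xout[right] - tx[n])
  }
  val
}

#' Subtract a fitted trend from a series
#'
#' @param x numeric observations.
#' @param trend a [TrendModel-class] aligned with `x`.
#' @return `x - trendFitted(trend)`; missing observations stay missing.
#' @export
detrend <- function(x, trend) {
  if (length(x) != length(trend@fitted))
    stop("series and trend have different lengths")
  x - trend@fitted
}

#' Smooth a series with a moving-average or low-pass filter
#'
#' Optional pre-treatment for one-off outbreaks or noisy observations.
#' `moving_average` is a centred window mean that shrinks symmetrically at
#' the edges; missing values are excluded from each window mean (the window
#' renormalises over the available points), and a fully missing window
#' yields a missing value. `lowpass` is a zero-phase second-order
#' Butterworth filter (applied forward and backward, so no phase shift) with
#' the cutoff in cycles per year; it requires a gap-free series.
#'
#' @param x numeric observations.
#' @param method `"moving_average"` or `"lowpass"`.
#' @param windowOrCutoff odd window length (moving average) or cutoff in
#'   cycles/year, strictly between 0 and `P/2` (lowpass).
#' @param P sub-year units per year (needed for the lowpass cutoff).
#' @return smoothed numeric vector, same length.
#' @export
smoothSeries <- function(x, method = c("moving_average", "lowpass"),
                         windowOrCutoff, P = 12L) {
  method <- match.arg(method)
  n <- length(x)
  if (method == "moving_average") {
    w <- windowOrCutoff
    if (w != round(w) || w %% 2 == 0 || w < 3 || w > n)
      stop("window must be an odd integer >= 3 and <= the series length")
    h <- (w - 1) / 2
    out <- vapply(seq_len(n), function(i) {
      he <- min(h, i - 1, n - i)     # shrink symmetrically at the edges
      win <- x[(i - he):(i + he)]
      if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
    }, numeric(1))
    out
  } else {
    cutoff <- windowOrCutoff
    if (cutoff <= 0 || cutoff >= P / 2)
      stop("lowpass cutoff must lie strictly between 0 and P/2 cycles/year")
    if (anyNA(x))
      stop("lowpass filtering requires a gap-free series; ",
           "interpolate or use the moving average first")
    bf <- signal::butter(2, cutoff / (P / 2), type = "low")
    as.numeric(signal::filtfilt(bf, x))
  }
}
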