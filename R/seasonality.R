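# Harmonic (partial Fourier) seasonality. The series is decomposed into
# sinusoids at 1, 2 and 4 cycles/year (12-, 6- and 3-month cycles) by least
# squares and reported as amplitude and phase rather than sine/cosine
# regression coefficients: component k is A_k * cos(2*pi*k*t - phi_k), so a
# pure annual harmonic peaks at month 12 * phi_1 / (2*pi), with month 0 at
# the start of January.

#' Fit harmonics to a (detrended) series
#'
#' Least-squares fit of `{1, cos(2*pi*k*t), sin(2*pi*k*t)}` for each
#' frequency `k`, converted to amplitude/phase form: `A_k = sqrt(a^2 + b^2)`
#' and `phi_k = atan2(b, a) mod 2*pi`, so component `k` equals
#' `A_k * cos(2*pi*k*t - phi_k)`.
#'
#' @param x numeric observations, usually detrended (missing allowed).
#' @param t fractional-year time axis, same length.
#' @param frequencies cycles per year, default `c(1, 2, 4)` (12-, 6- and
#'   3-month cycles).
#' @param P sub-year units per year.
#' @return a [HarmonicModel-class]; `meanLevel` is the fitted intercept.
#' @examples
#' t <- 2000 + (seq_len(120) - 0.5) / 12
#' m <- fitHarmonics(3 * cos(2 * pi * t - pi / 3), t)
#' amplitudes(m)  # ~ (3, 0, 0)
#' @export
fitHarmonics <- function(x, t, frequencies = c(1, 2, 4), P = 12L) {
  if (length(x) != length(t)) stop("x and t must have equal length")
  if (anyDuplicated(frequencies)) stop("duplicate harmonic frequencies")
  K <- length(frequencies)
  if (diff(range(t)) + 1 / P < 2 - 1e-9)
    stop("need at least 2 complete years of data")
  obs <- which(!is.na(x))
  if (length(obs) < 2L * (2L * K + 1L))
    stop(sprintf("need at least %d non-missing points for %d harmonics",
                 2L * (2L * K + 1L), K))
  X <- cbind(1, do.call(cbind, lapply(frequencies, function(k)
    cbind(cos(2 * pi * k * t), sin(2 * pi * k * t)))))
  fit <- stats::lm.fit(X[obs, , drop = FALSE], x[obs])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  a <- beta[seq(2L, by = 2L, length.out = K)]
  b <- beta[seq(3L, by = 2L, length.out = K)]
  A <- sqrt(a^2 + b^2)
  phi <- .wrapPhase(ifelse(A > 0, atan2(b, a), 0))
  new("HarmonicModel", meanLevel = unname(beta[1L]),
      frequencies = as.numeric(frequencies),
      amplitudes = unname(A), phases = unname(phi),
      periodicity = as.integer(P))
}

# within-year position -> months in [0, 12); a refined optimum a hair below
# u = 1 is the same calendar instant as month 0
.monthOf <- function(u) {
  m <- (12 * u) %% 12
  m[m >= 12 - 1e-9] <- 0
  m
}

# closed-form signature as a function of within-year position u in [0, 1);
# periodic, so any real u is accepted
signatureFunction <- function(model) {
  A <- model@amplitudes; phi <- model@phases; k <- model@frequencies
  m <- model@meanLevel
  function(u) {
    s <- rep(m, length(u))
    for (i in seq_along(k)) s <- s + A[i] * cos(2 * pi * k[i] * u - phi[i])
    s
  }
}

#' Evaluate the harmonic component on a time axis
#'
#' @param model a [HarmonicModel-class].
#' @param t fractional-year time axis.
#' @param includeMean add the model's mean level (default `TRUE`).
#' @return numeric vector of the seasonal component at `t`.
#' @export
evalHarmonics <- function(model, t, includeMean = TRUE) {
  out <- if (includeMean) rep(model@meanLevel, length(t)) else numeric(length(t))
  for (i in seq_along(model@frequencies))
    out <- out + model@amplitudes[i] *
      cos(2 * pi * model@frequencies[i] * t - model@phases[i])
  out
}

#' Average seasonal signature of a harmonic model
#'
#' Evaluates `meanLevel + sum_k A_k cos(2*pi*k*u - phi_k)` on a uniform
#' within-year grid: the average within-year profile with year-to-year
#' variation removed.
#'
#' @param model a [HarmonicModel-class].
#' @param resolution grid points per year (default 1200; must be at least
#'   `10 * P`).
#' @return a [SeasonalSignature-class].
#' @export
seasonalSignature <- function(model, resolution = 1200L) {
  if (resolution < 10L * model@periodicity)
    stop("resolution must be at least 10 * periodicity")
  u <- (seq_len(resolution) - 1) / resolution
  new("SeasonalSignature", grid = u, values = signatureFunction(model)(u),
      model = model)
}

#' Relative amplitude of a seasonal wave
#'
#' The wave height (peak minus trough) divided by the peak value: a
#' dimensionless seasonal-strength measure comparable across sites with very
#' different absolute burdens. Lies in `[0, 1]` when the trough is
#' non-negative; exceeds 1 for a negative trough (flagged by the caller,
#' never clipped).
#'
#' @param peakValue,troughValue signature values at the peak and trough;
#'   requires `peakValue > 0` and `peakValue >= troughValue`.
#' @return `(peakValue - troughValue) / peakValue`.
#' @examples
#' relativeAmplitude(13, 7)  # 6/13
#' @export
relativeAmplitude <- function(peakValue, troughValue) {
  if (peakValue <= 0) stop("amplitude undefined for non-positive peak")
  if (peakValue < troughValue) stop("peak value must be >= trough value")
  (peakValue - troughValue) / peakValue
}

#' Locate peaks and troughs of a seasonal signature
#'
#' Finds local extrema on the periodic (wrap-around aware) grid and refines
#' each with Brent optimisation of the closed-form signature, so reported
#' times are not limited by the grid resolution. The primary peak is the
#' global maximum and the primary trough the global minimum; a secondary
#' peak (bimodal signature) is the highest remaining local maximum separated
#' from the primary by at least one month on both sides whose topographic
#' prominence exceeds 5\% of the primary wave height. Times are in months
#' (`12 * u`, month 0 = start of January); on an exact plateau the earliest
#' within-year time is reported. Relative amplitudes use
#' [relativeAmplitude()]; a non-positive peak value leaves the amplitude
#' `NA` with flag `"undefined"`.
#'
#' @param signature a [SeasonalSignature-class].
#' @return a [PeakSet-class]. An (effectively) constant signature — range
#'   not exceeding `1e-12 * |mean level|` — yields a degenerate `PeakSet`
#'   with amplitude 0 and undefined times.
#' @export
findPeaks <- function(signature) {
  v <- signature@values
  u <- signature@grid
  model <- signature@model
  f <- signatureFunction(model)
  if (diff(range(v)) <= 1e-12 * max(abs(model@meanLevel), 1e-300)) {
    return(new("PeakSet", peakTime = NA_real_, peakValue = model@meanLevel,
               troughTime = NA_real_, troughValue = model@meanLevel,
               amplitude = 0, amplitudeFlag = "degenerate",
               secondaryTime = numeric(0), secondaryValue = numeric(0),
               secondaryAmplitude = numeric(0), degenerate = TRUE))
  }
  n <- length(v)
  du <- 1 / n
  left <- v[c(n, seq_len(n - 1L))]
  right <- v[c(seq.int(2L, n), 1L)]
  refine <- function(i, fn) {
    opt <- stats::optimize(fn, lower = u[i] - du, upper = u[i] + du,
                           maximum = TRUE, tol = 1e-10)
    list(u = opt$maximum %% 1, value = opt$objective)
  }
  maxIdx <- which(v > left & v >= right)   # earliest index of any plateau
  if (!length(maxIdx)) maxIdx <- which.max(v)
  peaks <- lapply(maxIdx, refine, fn = f)
  minIdx <- which(v < left & v <= right)
  if (!length(minIdx)) minIdx <- which.min(v)
  troughs <- lapply(minIdx, function(i)
    { r <- refine(i, function(z) -f(z)); r$value <- -r$value; r })
  pv <- vapply(peaks, `[[`, numeric(1), "value")
  best <- which(pv == max(pv))
  best <- best[which.min(vapply(peaks[best], `[[`, numeric(1), "u"))]
  tv <- vapply(troughs, `[[`, numeric(1), "value")
  worst <- which(tv == min(tv))
  worst <- worst[which.min(vapply(troughs[worst], `[[`, numeric(1), "u"))]
  peak <- peaks[[best]]; trough <- troughs[[worst]]
  waveHeight <- peak$value - trough$value

  amp <- NA_real_; flag <- "undefined"
  if (peak$value > 0) {
    amp <- relativeAmplitude(peak$value, trough$value)
    flag <- if (trough$value < 0) "exceeds_one" else "ok"
  }

  secT <- secV <- secA <- numeric(0)
  if (length(maxIdx) > 1L) {
    pIdx <- maxIdx[best]
    cand <- setdiff(seq_along(maxIdx), best)
    # topographic prominence on the circular grid: candidate value minus the
    # higher of the lowest points along the two paths to the primary peak
    prom <- vapply(cand, function(ci) {
      i <- maxIdx[ci]; p <- pIdx
      fwd <- if (i <= p) v[i:p] else v[c(i:n, 1:p)]
      bwd <- if (i >= p) v[p:i] else v[c(p:n, 1:i)]
      peaks[[ci]]$value - max(min(fwd), min(bwd))
    }, numeric(1))
    gap <- vapply(cand, function(ci) {
      d <- abs(peaks[[ci]]$u - peak$u) %% 1
      min(d, 1 - d)
    }, numeric(1))
    ok <- which(gap >= 1 / 12 - 1e-12 & prom > 0.05 * waveHeight)
    if (length(ok)) {
      sv <- vapply(peaks[cand[ok]], `[[`, numeric(1), "value")
      pick <- cand[ok][which.max(sv)]
      secT <- .monthOf(peaks[[pick]]$u)
      secV <- peaks[[pick]]$value
      secA <- if (secV > 0) relativeAmplitude(secV, trough$value) else NA_real_
    }
  }
  new("PeakSet",
      peakTime = .monthOf(peak$u), peakValue = peak$value,
      troughTime = .monthOf(trough$u), troughValue = trough$value,
      amplitude = amp, amplitudeFlag = flag,
      secondaryTime = secT, secondaryValue = secV, secondaryAmplitude = secA,
      degenerate = FALSE)
}

#' Combined trend-plus-seasonality model on the calendar
#'
#' The fitted trend plus the harmonic component at every calendar point —
#' the smooth model curve overlaid on the raw series.
#'
#' @param trend a [TrendModel-class].
#' @param harmonics a [HarmonicModel-class].
#' @param t fractional-year calendar; defaults to the trend's own axis and
#'   must match it.
#' @return numeric vector of model values at `t`.
#' @export
compositeModel <- function(trend, harmonics, t = trend@time) {
  if (length(t) != length(trend@time) ||
      max(abs(t - trend@time)) > 1e-9)
    stop("calendar is not aligned with the trend model")
  trend@fitted + evalHarmonics(harmonics, t, includeMean = TRUE)
}

#' Peak-timing stationarity diagnostic
#'
#' Harmonic seasonal parameters are only meaningful over a reasonably
#' stationary analysis period. This diagnostic reports, for each complete
#' year, the within-year timing (months) of that year's maximum of the
#' detrended observations, and the least-squares drift of peak timing in
#' months per year after circular unwrapping (year-to-year differences
#' mapped to `(-6, 6]` months, so a December/January alternation does not
#' masquerade as a six-month shift). A large drift suggests splitting the
#' series into smaller, stationary units; the diagnostic only reports, it
#' never splits.
#'
#' @param x numeric observations.
#' @param years,subunits calendar columns aligned with `x`.
#' @param P sub-year units per year.
#' @param trendOrder polynomial order used for detrending (default 3).
#' @return list: `years` (complete years used), `peakTimes` (raw months),
#'   `unwrapped` (circularly unwrapped months), `driftSlope` (months/year).
#' @export
stationarityDiagnostic <- function(x, years, subunits, P = max(subunits),
                                   trendOrder = 3L) {
  t <- fracYearAxis(years, subunits, P)
  d <- detrend(x, fitPolynomialTrend(x, t, order = trendOrder))
  tab <- tapply(subunits, years, function(s) length(unique(s)))
  full <- as.integer(names(tab)[tab == P])
  if (length(full) < 4L) stop("need at least 4 complete years")
  pt <- vapply(full, function(y) {
    sel <- years == y & !is.na(d)
    if (!any(sel)) return(NA_real_)
    (subunits[sel][which.max(d[sel])] - 0.5) * 12 / P
  }, numeric(1))
  keep <- !is.na(pt)
  full <- full[keep]; pt <- pt[keep]
  unwrapped <- pt
  for (i in seq_along(pt)[-1])
    unwrapped[i] <- unwrapped[i - 1] + circularMonthDiff(pt[i] - pt[i - 1])
  slope <- unname(stats::coef(stats::lm(unwrapped ~ full))[2])
  list(years = full, peakTimes = pt, unwrapped = unwrapped,
       driftSlope = slope)
}

#' Average-year profile across categories
#'
#' For panels sharing a calendar — one per category, e.g. age groups from
#' workbook sheets — computes the mean over years of each category's series
#' at every within-year unit: the category profile of an average year.
#'
#' @param panels list of [TimeSeriesPanel-class] objects sharing calendar
#'   and sites, one per category (list names label the categories).
#' @param site site name or column index to profile (default first column).
#' @return numeric matrix, `P` rows (within-year units) by one column per
#'   category; missing observations are excluded from the means.
#' @export
averageYearByCategory <- function(panels, site = 1L) {
  stopifnot(length(panels) >= 1L)
  ref <- panels[[1L]]
  for (p in panels[-1L]) {
    if (!identical(p@years, ref@years) || !identical(p@subunits, ref@subunits) ||
        !identical(p@periodicity, ref@periodicity))
      stop("panels do not share a calendar")
  }
  P <- ref@periodicity
  out <- vapply(panels, function(p) {
    x <- p@values[, site]
    vapply(seq_len(P), function(m)
      mean(x[p@subunits == m], na.rm = TRUE), numeric(1))
  }, numeric(P))
  out <- matrix(out, nrow = P)
  colnames(out) <- if (!is.null(names(panels))) names(panels) else
    paste0("category", seq_along(panels))
  rownames(out) <- seq_len(P)
  out
}
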