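# Synthetic multi-site panels with analytic ground truth: every other
# module is testable against known trend, harmonic, peak and excess values
# without any external data. Defaults emulate a multi-site mortality panel:
# a mean burden of 10 (e.g. deaths per 100,000 per month), a gentle cubic
# trend, dominant annual seasonality with semi-annual and quarterly
# harmonics A = (3, 1, 0.5), Gaussian observation noise at 5% of the mean,
# and a latitude-linked peak-timing gradient.

#' Configure a synthetic panel
#'
#' @param nSites number of sites.
#' @param years number of complete calendar years.
#' @param periodicity sub-year units per year (12 = monthly).
#' @param startYear first calendar year.
#' @param meanLevel mean burden level (series units), recycled per site.
#' @param trendCoef ascending-power polynomial coefficients over centred
#'   fractional-year time, shared or a list per site.
#' @param amplitudes,frequencies harmonic amplitudes and frequencies
#'   (cycles/year), shared across sites.
#' @param phases per-site list/matrix of phases in radians, or `NULL` to use
#'   the latitude rule: peak month of the annual harmonic =
#'   `phaseIntercept + phaseSlope * latitude`, higher harmonics phase-locked
#'   to twice/four times the annual phase.
#' @param latitudes,longitudes site coordinates; defaults spread sites along
#'   a latitudinal gradient.
#' @param phaseSlope months of annual peak shift per degree latitude
#'   (default 0.1).
#' @param phaseIntercept annual peak month at latitude 0 (default 6).
#' @param noiseSd Gaussian noise level; a fraction of `meanLevel` when
#'   `noiseType = "fraction"` (default 0.05), absolute units otherwise.
#' @param noiseType `"fraction"` or `"absolute"`.
#' @param pandemics list of injections, each
#'   `list(site =, window = c(y1, s1, y2, s2), total =)`; the burden is
#'   added with a half-sine shape over the window, summing to `total`.
#' @param missingRate probability in `[0, 1)` that a non-injected point is
#'   set missing.
#' @param seed mandatory integer seed; identical seeds give bit-identical
#'   panels.
#' @param groups optional per-site group labels for the geo table.
#' @return a [SynthConfig-class].
#' @export
synthConfig <- function(nSites = 5L, years = 20L, periodicity = 12L,
                        startYear = 2000L, meanLevel = 10,
                        trendCoef = c(0, 0.05, 0, 0.002),
                        amplitudes = c(3, 1, 0.5), frequencies = c(1, 2, 4),
                        phases = NULL,
                        latitudes = seq(-40, 40, length.out = nSites),
                        longitudes = seq(-70, -40, length.out = nSites),
                        phaseSlope = 0.1, phaseIntercept = 6,
                        noiseSd = 0.05, noiseType = c("fraction", "absolute"),
                        pandemics = list(), missingRate = 0, seed,
                        groups = character(0)) {
  noiseType <- match.arg(noiseType)
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must lie in [0, 1)")
  if (length(amplitudes) != length(frequencies))
    stop("amplitudes and frequencies must align")
  meanLevel <- rep_len(meanLevel, nSites)
  if (!is.list(trendCoef)) trendCoef <- rep(list(trendCoef), nSites)
  if (is.null(phases)) {
    peakMonth <- (phaseIntercept + phaseSlope * latitudes) %% 12
    phi1 <- 2 * pi * peakMonth / 12
    phases <- lapply(phi1, function(p)
      (p * frequencies / frequencies[1]) %% (2 * pi))
  } else if (!is.list(phases)) {
    phases <- rep(list(phases), nSites)
  }
  cfg <- list(nSites = as.integer(nSites), years = as.integer(years),
              periodicity = as.integer(periodicity),
              startYear = as.integer(startYear), meanLevel = meanLevel,
              trendCoef = trendCoef, amplitudes = amplitudes,
              frequencies = frequencies, phases = phases,
              latitudes = latitudes, longitudes = longitudes,
              noiseSd = noiseSd, noiseType = noiseType,
              pandemics = pandemics, missingRate = missingRate,
              seed = as.integer(seed), groups = as.character(groups))
  new("SynthConfig", config = cfg)
}

# deterministic (noise-free, injection-free) component, one column per site
.synthDeterministic <- function(cfg) {
  n <- cfg$years * cfg$periodicity
  yr <- rep(cfg$startYear + seq_len(cfg$years) - 1L, each = cfg$periodicity)
  su <- rep(seq_len(cfg$periodicity), cfg$years)
  t <- fracYearAxis(yr, su, cfg$periodicity)
  tc <- t - mean(range(t))
  det <- vapply(seq_len(cfg$nSites), function(i) {
    v <- cfg$meanLevel[i] +
      as.numeric(outer(tc, seq_along(cfg$trendCoef[[i]]) - 1, `^`) %*%
                   cfg$trendCoef[[i]])
    for (j in seq_along(cfg$frequencies))
      v <- v + cfg$amplitudes[j] *
        cos(2 * pi * cfg$frequencies[j] * t - cfg$phases[[i]][j])
    v
  }, numeric(n))
  list(years = yr, subunits = su, t = t, values = matrix(det, nrow = n))
}

# half-sine injection weights over m points, summing to total
.injectionShape <- function(m, total) {
  w <- sin(pi * (seq_len(m) - 0.5) / m)
  total * w / sum(w)
}

#' Generate a synthetic multi-site panel
#'
#' Values are trend + harmonics + Gaussian noise + injected event burdens;
#' missingness is then applied at random non-injected points. The ground
#' truth is computed analytically from the configuration, independent of the
#' noise draw.
#'
#' @param config a [SynthConfig-class].
#' @return list with elements `panel` ([TimeSeriesPanel-class]), `geo`
#'   ([GeoTable-class]) and `truth`, where `truth` holds per site: the
#'   noise-free deterministic values (`deterministic`, injections included;
#'   `baseline`, injections excluded), the true harmonic parameters, the
#'   true peak time and relative amplitude (from [truthPeakParameters()]),
#'   and the injected totals.
#' @export
generatePanel <- function(config) {
  cfg <- config@config
  base <- .synthDeterministic(cfg)
  n <- nrow(base$values)
  det <- base$values           # with injections
  clean <- base$values         # without injections
  injected <- matrix(FALSE, n, cfg$nSites)
  injTotals <- numeric(cfg$nSites)
  for (pd in cfg$pandemics) {
    i <- if (is.character(pd$site)) match(pd$site, .synthSiteNames(cfg))
         else pd$site
    idx <- windowIndices(base$years, base$subunits, cfg$periodicity,
                         list(pd$window))
    det[idx, i] <- det[idx, i] + .injectionShape(length(idx), pd$total)
    injected[idx, i] <- TRUE
    injTotals[i] <- injTotals[i] + pd$total
  }
  sd <- if (cfg$noiseType == "fraction") cfg$noiseSd * cfg$meanLevel
        else rep_len(cfg$noiseSd, cfg$nSites)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(cfg$seed)
  vals <- det + vapply(seq_len(cfg$nSites),
                       function(i) stats::rnorm(n, 0, sd[i]), numeric(n))
  if (cfg$missingRate > 0) {
    miss <- matrix(stats::runif(n * cfg$nSites) < cfg$missingRate,
                   n, cfg$nSites) & !injected
    vals[miss] <- NA_real_
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  sites <- .synthSiteNames(cfg)
  colnames(vals) <- sites
  panel <- TimeSeriesPanel(base$years, base$subunits, vals,
                           periodicity = cfg$periodicity, siteNames = sites)
  geo <- GeoTable(sites, cfg$latitudes, cfg$longitudes,
                  groups = if (length(cfg$groups)) cfg$groups else character(0))
  peaks <- truthPeakParameters(config)
  truth <- list(
    years = base$years, subunits = base$subunits, t = base$t,
    deterministic = `colnames<-`(det, sites),
    baseline = `colnames<-`(clean, sites),
    harmonics = lapply(seq_len(cfg$nSites), function(i)
      list(meanLevel = cfg$meanLevel[i], frequencies = cfg$frequencies,
           amplitudes = cfg$amplitudes, phases = cfg$phases[[i]])),
    peaks = peaks, injectedTotals = injTotals)
  list(panel = panel, geo = geo, truth = truth)
}

.synthSiteNames <- function(cfg) sprintf("S%02d", seq_len(cfg$nSites))

#' Analytic peak parameters of a configured signature
#'
#' The independent oracle for peak detection: for each site, the noise-free
#' seasonal signature `meanLevel + sum_k A_k cos(2*pi*k*u - phi_k)` is
#' searched exhaustively on a 100,000-point within-year grid, then the peak
#' and trough are sharpened by golden-section search; the relative amplitude
#' is `(peak - trough) / peak`.
#'
#' @param config a [SynthConfig-class].
#' @param gridSize exhaustive grid resolution (default `1e5`).
#' @return data.frame, one row per site: `site`, `peakTime` (months),
#'   `peakValue`, `troughTime`, `troughValue`, `relativeAmplitude` (`NA`,
#'   with `defined = FALSE`, for an all-zero-amplitude signature).
#' @export
truthPeakParameters <- function(config, gridSize = 1e5L) {
  cfg <- config@config
  out <- lapply(seq_len(cfg$nSites), function(i) {
    f <- function(u) {
      s <- rep(cfg$meanLevel[i], length(u))
      for (j in seq_along(cfg$frequencies))
        s <- s + cfg$amplitudes[j] *
          cos(2 * pi * cfg$frequencies[j] * u - cfg$phases[[i]][j])
      s
    }
    if (all(cfg$amplitudes == 0))
      return(data.frame(site = .synthSiteNames(cfg)[i], peakTime = NA_real_,
                        peakValue = cfg$meanLevel[i], troughTime = NA_real_,
                        troughValue = cfg$meanLevel[i],
                        relativeAmplitude = 0, defined = FALSE))
    u <- (seq_len(gridSize) - 1) / gridSize
    v <- f(u)
    du <- 1 / gridSize
    pk <- goldenSectionMax(f, u[which.max(v)] - du, u[which.max(v)] + du)
    tr <- goldenSectionMax(function(z) -f(z),
                           u[which.min(v)] - du, u[which.min(v)] + du)
    tr$value <- -tr$value
    ra <- if (pk$value > 0) (pk$value - tr$value) / pk$value else NA_real_
    data.frame(site = .synthSiteNames(cfg)[i],
               peakTime = 12 * (pk$u %% 1), peakValue = pk$value,
               troughTime = 12 * (tr$u %% 1), troughValue = tr$value,
               relativeAmplitude = ra, defined = pk$value > 0)
  })
  do.call(rbind, out)
}

# plain golden-section maximisation on [lo, hi]; deliberately not Brent so
# the oracle's refinement shares no code path with findPeaks()
goldenSectionMax <- function(f, lo, hi, tol = 1e-12) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c); fd <- f(d)
  while (b - a > tol) {
    if (fc > fd) { b <- d; d <- c; fd <- fc
                   c <- b - gr * (b - a); fc <- f(c) }
    else { a <- c; c <- d; fc <- fd
           d <- a + gr * (b - a); fd <- f(d) }
  }
  u <- (a + b) / 2
  list(u = u, value = f(u))
}
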