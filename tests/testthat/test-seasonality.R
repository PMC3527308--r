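test_that("harmonic fits recover pure sinusoids exactly", {
  t <- monthlyTime(10L)
  m <- fitHarmonics(3 * cos(2 * pi * t - pi / 3), t)
  expect_equal(amplitudes(m)[1], 3, tolerance = 1e-6)
  expect_equal(phases(m)[1], pi / 3, tolerance = 1e-6)
  expect_lt(max(amplitudes(m)[2:3]), 1e-6)

  z <- fitHarmonics(numeric(length(t)), t)
  expect_equal(amplitudes(z), c(0, 0, 0))
  expect_equal(z@meanLevel, 0)

  m2 <- fitHarmonics(2 * cos(4 * pi * t), t)
  expect_equal(amplitudes(m2)[2], 2, tolerance = 1e-6)
  expect_lt(max(amplitudes(m2)[c(1, 3)]), 1e-6)
})

test_that("harmonic fitting enforces data preconditions", {
  t <- monthlyTime(10L)
  expect_error(fitHarmonics(cos(2 * pi * t), t, frequencies = c(1, 1, 2)),
               "duplicate")
  x <- rep(NA_real_, length(t)); x[1:10] <- 1
  expect_error(fitHarmonics(x, t), "at least 14")
  t1 <- monthlyTime(1L)
  expect_error(fitHarmonics(cos(2 * pi * t1), t1), "2 complete years")
})

test_that("parameter recovery degrades gracefully with noise and is exact without", {
  t <- monthlyTime(20L)
  A <- c(3, 1, 0.5); phi <- c(1.1, 2.3, 0.7)
  truth <- 10 + A[1] * cos(2 * pi * t - phi[1]) +
    A[2] * cos(4 * pi * t - phi[2]) + A[3] * cos(8 * pi * t - phi[3])
  for (sigma in c(0, 0.2, 0.5)) {
    set.seed(100 + round(100 * sigma))
    m <- fitHarmonics(truth + rnorm(length(t), 0, sigma), t)
    tol <- max(1e-6, 3 * sigma * sqrt(2 / length(t)))
    expect_lt(max(abs(amplitudes(m) - A)), tol)
    dphi <- abs(((phases(m) - phi + pi) %% (2 * pi)) - pi)
    expect_lt(max(dphi), max(1e-6, 3 * sigma))
  }
})

test_that("the seasonal signature is the periodic closed form on a grid", {
  flat <- new("HarmonicModel", meanLevel = 4, frequencies = c(1, 2, 4),
              amplitudes = c(0, 0, 0), phases = c(0, 0, 0),
              periodicity = 12L)
  s <- seasonalSignature(flat)
  expect_equal(s@values, rep(4, 1200))

  m1 <- new("HarmonicModel", meanLevel = 0, frequencies = 1, amplitudes = 1,
            phases = 0, periodicity = 12L)
  s1 <- seasonalSignature(m1)
  expect_equal(s1@grid[which.max(s1@values)], 0, tolerance = 1 / 1200)

  m2 <- new("HarmonicModel", meanLevel = 5, frequencies = 2, amplitudes = 1,
            phases = 0.8, periodicity = 12L)
  s2 <- seasonalSignature(m2, resolution = 1200L)
  half <- 600L
  expect_equal(s2@values[1:600], s2@values[601:1200], tolerance = 1e-9)

  expect_error(seasonalSignature(m1, resolution = 100L), "at least 10")
})

test_that("relative amplitude follows the wave-height-over-peak formula", {
  expect_equal(relativeAmplitude(13, 7), 6 / 13)
  expect_equal(relativeAmplitude(5, 5), 0)
  expect_equal(relativeAmplitude(4, -1), 1.25)  # may exceed 1, never clipped
  expect_error(relativeAmplitude(0, -1), "non-positive peak")
  expect_error(relativeAmplitude(-2, -3), "non-positive peak")
})

test_that("peak detection matches the phase convention and flags edge cases", {
  # pure annual harmonic peaking in July: u_max = 6.5/12
  phi <- 2 * pi * 6.5 / 12
  m <- new("HarmonicModel", meanLevel = 10, frequencies = 1, amplitudes = 3,
           phases = phi, periodicity = 12L)
  pk <- findPeaks(seasonalSignature(m))
  expect_equal(pk@peakTime, 6.5, tolerance = 0.02)
  expect_length(pk@secondaryTime, 0L)
  expect_equal(pk@amplitude, 2 * 3 / (10 + 3), tolerance = 1e-9)
  expect_identical(pk@amplitudeFlag, "ok")

  flat <- new("HarmonicModel", meanLevel = 2, frequencies = 1, amplitudes = 0,
              phases = 0, periodicity = 12L)
  dg <- findPeaks(seasonalSignature(flat))
  expect_true(dg@degenerate)
  expect_equal(dg@amplitude, 0)

  neg <- new("HarmonicModel", meanLevel = 1, frequencies = 1, amplitudes = 2,
             phases = 0, periodicity = 12L)
  fneg <- findPeaks(seasonalSignature(neg))
  expect_identical(fneg@amplitudeFlag, "exceeds_one")
  expect_gt(fneg@amplitude, 1)

  undef <- new("HarmonicModel", meanLevel = -5, frequencies = 1,
               amplitudes = 2, phases = 0, periodicity = 12L)
  fu <- findPeaks(seasonalSignature(undef))
  expect_identical(fu@amplitudeFlag, "undefined")
  expect_true(is.na(fu@amplitude))
})

test_that("bimodal signatures yield a secondary peak matching the grid oracle", {
  m <- new("HarmonicModel", meanLevel = 10, frequencies = c(1, 2),
           amplitudes = c(1, 0.8), phases = c(0, 0), periodicity = 12L)
  pk <- findPeaks(seasonalSignature(m))
  orc <- oraclePeakSearch(10, c(1, 2), c(1, 0.8), c(0, 0))
  circ <- abs(pk@peakTime - orc$peakTime) %% 12
  expect_lt(min(circ, 12 - circ), orc$gridStepMonths)
  expect_equal(pk@peakValue, orc$peakValue, tolerance = 1e-9)
  expect_length(pk@secondaryTime, 1L)
  expect_equal(pk@secondaryTime, 6, tolerance = 0.02)
  expect_lte(pk@secondaryValue, pk@peakValue)
})

test_that("peak times of pure annual models equal 12*phi/(2*pi) months", {
  set.seed(9)
  for (i in 1:20) {
    phi <- runif(1, 0, 2 * pi)
    m <- new("HarmonicModel", meanLevel = 5, frequencies = 1,
             amplitudes = runif(1, 0.5, 3), phases = phi, periodicity = 12L)
    pk <- findPeaks(seasonalSignature(m))
    d <- abs(pk@peakTime - 12 * phi / (2 * pi))
    expect_lt(min(d, 12 - d), 12 / 1200)
  }
})

test_that("the composite model is trend plus harmonics on the shared calendar", {
  t <- monthlyTime(20L)
  zeroH <- new("HarmonicModel", meanLevel = 0, frequencies = c(1, 2, 4),
               amplitudes = c(0, 0, 0), phases = c(0, 0, 0),
               periodicity = 12L)
  tr <- fitPolynomialTrend(5 + 0.2 * (t - mean(t)), t, order = 3)
  expect_equal(compositeModel(tr, zeroH), trendFitted(tr))

  zeroT <- fitPolynomialTrend(numeric(length(t)), t, order = 0)
  sine <- new("HarmonicModel", meanLevel = 0, frequencies = 1,
              amplitudes = 2, phases = 1, periodicity = 12L)
  expect_equal(compositeModel(zeroT, sine), 2 * cos(2 * pi * t - 1),
               tolerance = 1e-9)
  expect_error(compositeModel(tr, sine, t = t + 1), "not aligned")

  # trend + 3 harmonics + noise: composite tracks the noise-free truth
  tc <- t - mean(range(t))
  truth <- 10 + 0.3 * tc + 0.01 * tc^3 + 3 * cos(2 * pi * t - 1) +
    cos(4 * pi * t - 2) + 0.5 * cos(8 * pi * t)
  set.seed(21)
  x <- truth + rnorm(length(t), 0, 0.05 * 3)
  fit <- fitPolynomialTrend(x, t, order = 3)
  harm <- fitHarmonics(detrend(x, fit), t)
  expect_gt(stats::cor(compositeModel(fit, harm), truth), 0.999)
})

test_that("peak-timing drift is reported with circular unwrapping", {
  cal <- monthlyCalendar(12L)
  t <- cal$years + (cal$subunits - 0.5) / 12
  set.seed(31)
  stationary <- 10 + 3 * cos(2 * pi * t - 2) + rnorm(length(t), 0, 0.5)
  d0 <- stationarityDiagnostic(stationary, cal$years, cal$subunits, 12L)
  expect_lt(abs(d0$driftSlope), 0.1)

  # peak shifting +0.5 month/year
  yearIdx <- cal$years - min(cal$years)
  phi <- 2 * pi * (3 + 0.5 * yearIdx) / 12
  set.seed(32)
  drifting <- 10 + 3 * cos(2 * pi * t - phi) + rnorm(length(t), 0, 0.3)
  dd <- stationarityDiagnostic(drifting, cal$years, cal$subunits, 12L)
  expect_equal(dd$driftSlope, 0.5, tolerance = 0.1)

  # December/January alternation must unwrap to ~0 drift, not +/- 6
  alt <- rep(0, length(t))
  alt[cal$subunits == 12 & yearIdx %% 2 == 0] <- 10
  alt[cal$subunits == 1 & yearIdx %% 2 == 1] <- 10
  da <- stationarityDiagnostic(alt, cal$years, cal$subunits, 12L,
                               trendOrder = 0L)
  expect_lt(abs(da$driftSlope), 0.5)
  expect_error(stationarityDiagnostic(stationary[1:36], cal$years[1:36],
                                      cal$subunits[1:36], 12L),
               "at least 4 complete years")
})

test_that("average-year profiles aggregate categories over years", {
  cal <- monthlyCalendar(2L)
  a <- matrix(rep(1:12, 2), ncol = 1, dimnames = list(NULL, "X"))
  pa <- makeMonthlyPanel(a)
  avg1 <- averageYearByCategory(list(young = pa))
  expect_equal(unname(avg1[, 1]), as.numeric(1:12))

  pb <- makeMonthlyPanel(matrix(7, 24, 1, dimnames = list(NULL, "X")))
  avg2 <- averageYearByCategory(list(young = pa, old = pb))
  expect_identical(colnames(avg2), c("young", "old"))
  expect_equal(unname(avg2[, "old"]), rep(7, 12))

  withNA <- a; withNA[1, 1] <- NA   # January of year 1 missing
  pc <- makeMonthlyPanel(withNA)
  avg3 <- averageYearByCategory(list(all = pc))
  expect_equal(unname(avg3[1, 1]), unname(a[13, 1]))  # remaining January

  pShift <- TimeSeriesPanel(cal$years + 1L, cal$subunits, a)
  expect_error(averageYearByCategory(list(pa, pShift)), "calendar")
})
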