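test_that("exclusion masks mark exactly the requested calendar points", {
  cal <- monthlyCalendar(11L, startYear = 2000L)
  m <- exclusionMask(cal$years, cal$subunits, 12L, windows = c(2009, 2010))
  expect_identical(sum(m), 24L)
  expect_true(all(cal$years[m] %in% c(2009, 2010)))

  none <- exclusionMask(cal$years, cal$subunits, 12L, windows = NULL)
  expect_false(any(none))

  span <- exclusionMask(cal$years, cal$subunits, 12L,
                        windows = list(c(2004, 6, 2005, 2)))
  expect_identical(sum(span), 9L)

  expect_error(exclusionMask(cal$years, cal$subunits, 12L,
                             windows = 2000:2010),
               "fewer than 2 complete years")
  expect_error(exclusionMask(cal$years, cal$subunits, 12L, windows = 1995),
               "outside the calendar")
})

test_that("baselines fit only non-excluded points and evaluate everywhere", {
  cal <- monthlyCalendar(11L, startYear = 2000L)
  t <- cal$years + (cal$subunits - 0.5) / 12
  tc <- t - mean(range(t))
  truth <- 10 + 0.2 * tc + 3 * cos(2 * pi * t - 1) + cos(4 * pi * t - 2)
  mask <- exclusionMask(cal$years, cal$subunits, 12L, windows = c(2009, 2010))

  bl <- fitBaseline(truth, cal$years, cal$subunits, 12L, mask = mask)
  expect_equal(baselineValues(bl), truth, tolerance = 1e-6)
  expect_lt(residualScale(bl), 1e-8)

  spiked <- truth
  spiked[cal$years == 2009] <- spiked[cal$years == 2009] + 50
  blSpiked <- fitBaseline(spiked, cal$years, cal$subunits, 12L, mask = mask)
  expect_equal(baselineValues(blSpiked), baselineValues(bl),
               tolerance = 1e-9)
  blBiased <- fitBaseline(spiked, cal$years, cal$subunits, 12L)
  expect_gt(mean(abs(baselineValues(blBiased) - baselineValues(bl))), 0)
})

test_that("altering excluded observations cannot change the baseline", {
  cfg <- synthConfig(nSites = 1, years = 11, seed = 17)
  gen <- generatePanel(cfg)
  yr <- panelYears(gen$panel); su <- panelSubunits(gen$panel)
  x <- panelValues(gen$panel)[, 1]
  mask <- exclusionMask(yr, su, 12L, windows = c(2008, 2009))
  b1 <- fitBaseline(x, yr, su, 12L, mask = mask)
  x2 <- x
  set.seed(1)
  x2[mask] <- x2[mask] + runif(sum(mask), -1e6, 1e6)
  b2 <- fitBaseline(x2, yr, su, 12L, mask = mask)
  rel <- max(abs(baselineValues(b1) - baselineValues(b2))) /
    max(abs(baselineValues(b1)))
  expect_lt(rel, 1e-12)
  expect_lt(abs(residualScale(b1) - residualScale(b2)) /
              residualScale(b1), 1e-12)
})

test_that("prediction intervals follow the Student-t convention", {
  cfg <- synthConfig(nSites = 1, years = 50, seed = 23)
  gen <- generatePanel(cfg)
  x <- panelValues(gen$panel)[, 1]
  bl <- fitBaseline(x, panelYears(gen$panel), panelSubunits(gen$panel), 12L)
  pi95 <- predictionInterval(bl)
  half <- (pi95$upper - pi95$lower) / 2
  expect_equal(half[1] / residualScale(bl),
               stats::qt(0.975, bl@nFit - bl@nParams), tolerance = 1e-12)
  expect_true(all(pi95$upper > pi95$lower))

  # large n: the half-width approaches the normal limit 1.96 * s
  big <- generatePanel(synthConfig(nSites = 1, years = 200, seed = 24))
  xb <- panelValues(big$panel)[, 1]
  blb <- fitBaseline(xb, panelYears(big$panel), panelSubunits(big$panel), 12L)
  hb <- (predictionInterval(blb)$upper - baselineValues(blb))[1]
  expect_equal(hb / residualScale(blb), 1.959964, tolerance = 1e-3)
  wide <- predictionInterval(bl, level = 0.99)
  expect_true(all(wide$upper > pi95$upper) && all(wide$lower < pi95$lower))

  zero <- bl
  zero@residualScale <- 0
  p0 <- predictionInterval(zero)
  expect_equal(p0$lower, baselineValues(zero))
  expect_equal(p0$upper, baselineValues(zero))
})

test_that("anomalies are strict bound violations with signed magnitudes", {
  cal <- monthlyCalendar(4L)
  t <- cal$years + (cal$subunits - 0.5) / 12
  x <- 10 + 3 * cos(2 * pi * t - 1) + 0.5 * cos(4 * pi * t)
  bl <- fitBaseline(x, cal$years, cal$subunits, 12L)
  # noise-free fit: interval collapses, nothing inside it is flagged
  x1 <- x
  bounds <- predictionInterval(bl)
  empty <- detectAnomalies(x, bl, cal$years, cal$subunits)
  expect_identical(nrow(as.data.frame(empty)), 0L)

  x1[20] <- bounds$upper[20] + 5
  x1[30] <- bounds$lower[30] - 2
  x1[40] <- bounds$upper[40]       # exactly on the bound: not an anomaly
  cat1 <- detectAnomalies(x1, bl, cal$years, cal$subunits)
  df <- as.data.frame(cat1)
  expect_identical(df$index, c(20L, 30L))
  expect_identical(df$direction, c("above", "below"))
  expect_equal(df$magnitude, c(5, -2))

  onlyWin <- detectAnomalies(x1, bl, cal$years, cal$subunits,
                             restrictTo = list(c(2003, 1, 2003, 12)))
  expect_identical(as.data.frame(onlyWin)$index, 30L)
})

test_that("excess burden sums exceedance over the window and is additive", {
  cal <- monthlyCalendar(11L, startYear = 2000L)
  t <- cal$years + (cal$subunits - 0.5) / 12
  truth <- 10 + 3 * cos(2 * pi * t - 1)
  mask <- exclusionMask(cal$years, cal$subunits, 12L, windows = 2009)
  bl <- fitBaseline(truth, cal$years, cal$subunits, 12L, mask = mask)
  ex0 <- excessBurden(truth, bl, cal$years, cal$subunits, window = 2009)
  expect_equal(ex0$total, 0)
  expect_equal(excessBurden(truth, bl, cal$years, cal$subunits,
                            window = 2009, reference = "baseline")$total,
               0, tolerance = 1e-8)

  # inject +100 total, spread above the (collapsed) upper bound
  upper <- predictionInterval(bl)$upper
  inj <- truth
  w <- which(cal$years == 2009 & cal$subunits %in% 3:7)
  inj[w] <- upper[w] + 20
  ex1 <- excessBurden(inj, bl, cal$years, cal$subunits, window = 2009)
  expect_equal(ex1$total, 100, tolerance = 1e-6)

  exA <- excessBurden(inj, bl, cal$years, cal$subunits,
                      window = list(c(2009, 1, 2009, 6)))
  exB <- excessBurden(inj, bl, cal$years, cal$subunits,
                      window = list(c(2009, 7, 2009, 12)))
  expect_equal(exA$total + exB$total, ex1$total, tolerance = 1e-9)
  expect_error(excessBurden(inj, bl, cal$years, cal$subunits,
                            window = list()),
               "selects no calendar points")
})

test_that("raising the level widens intervals and cannot increase excess", {
  cfg <- synthConfig(nSites = 1, years = 11, seed = 29,
                     pandemics = list(list(site = 1,
                                           window = c(2008, 3, 2008, 8),
                                           total = 400)))
  gen <- generatePanel(cfg)
  yr <- panelYears(gen$panel); su <- panelSubunits(gen$panel)
  x <- panelValues(gen$panel)[, 1]
  mask <- exclusionMask(yr, su, 12L, windows = 2008)
  prev <- Inf
  for (lv in c(0.8, 0.9, 0.95, 0.99)) {
    bl <- fitBaseline(x, yr, su, 12L, mask = mask, level = lv)
    ex <- excessBurden(x, bl, yr, su, window = 2008)$total
    expect_lte(ex, prev + 1e-12)
    prev <- ex
  }
})
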