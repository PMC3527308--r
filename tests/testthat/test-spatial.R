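test_that("parameter tables have one complete row per site and a stable schema", {
  cfg <- synthConfig(nSites = 3, years = 8, seed = 51,
                     groups = c("south", "mid", "north"))
  gen <- generatePanel(cfg)
  tab <- buildParameterTable(gen$panel, gen$geo)
  df <- as.data.frame(tab)
  expect_identical(nrow(df), 3L)
  expect_false(anyNA(df$peak_time))
  expect_false(anyNA(df$relative_amplitude))
  expect_true(all(df$peak_time >= 0 & df$peak_time < 12))
  expect_identical(df$group, c("south", "mid", "north"))

  # optional analyses absent: same columns, NA values
  expect_true(all(c("total_excess", "n_anomalies_above",
                    "secondary_amplitude") %in% names(df)))
  expect_true(all(is.na(df$total_excess)))

  withEx <- buildParameterTable(gen$panel, gen$geo,
                                excess = c(S01 = 12.5))
  expect_identical(names(as.data.frame(withEx)), names(df))
  expect_equal(as.data.frame(withEx)$total_excess, c(12.5, NA, NA))
})

test_that("an all-missing site is flagged, not silently dropped", {
  cfg <- synthConfig(nSites = 3, years = 8, seed = 52)
  gen <- generatePanel(cfg)
  p <- gen$panel
  p@values[, 2] <- NA_real_
  tab <- as.data.frame(buildParameterTable(p, gen$geo))
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$amplitude_flag[2], "all_missing")
  expect_true(is.na(tab$peak_time[2]))
  expect_false(anyNA(tab$peak_time[c(1, 3)]))
})

test_that("mismatched analysis options across sites are rejected", {
  cfg <- synthConfig(nSites = 2, years = 8, seed = 53)
  gen <- generatePanel(cfg)
  r1 <- analyzeSite(gen$panel, 1, trendOrder = 3L)
  r2 <- analyzeSite(gen$panel, 2, trendOrder = 1L)
  expect_error(buildParameterTable(gen$panel, gen$geo, results = list(r1, r2)),
               "options differ")
})

test_that("site permutation permutes rows without changing values", {
  cfg <- synthConfig(nSites = 4, years = 8, seed = 54)
  gen <- generatePanel(cfg)
  t1 <- as.data.frame(buildParameterTable(gen$panel, gen$geo))
  perm <- c(3, 1, 4, 2)
  p2 <- TimeSeriesPanel(panelYears(gen$panel), panelSubunits(gen$panel),
                        panelValues(gen$panel)[, perm],
                        periodicity = 12L,
                        siteNames = siteNames(gen$panel)[perm])
  t2 <- as.data.frame(buildParameterTable(p2, gen$geo))
  reord <- t2[match(t1$site, t2$site), ]
  rownames(reord) <- NULL
  expect_equal(reord, t1)
})

test_that("map markers scale proportionally and peak-time colours are cyclic", {
  df <- data.frame(site = c("A", "B"), latitude = c(10, -10),
                   longitude = c(-50, -55), group = NA_character_,
                   mean_level = c(5, 8), linear_trend = c(0, 0),
                   peak_time = c(0.1, 11.9), peak_value = c(6, 9),
                   trough_time = c(6, 6), trough_value = c(4, 7),
                   relative_amplitude = c(0.2, 0.4),
                   amplitude_flag = "ok", stringsAsFactors = FALSE)
  tab <- new("SiteParameterTable", table = df)
  dest <- file.path(withr::local_tempdir(), "map.pdf")
  md <- plotMap(tab, dest = dest)
  expect_true(file.exists(dest))
  expect_equal(md$markerArea[2] / md$markerArea[1], 2, tolerance = 1e-12)
  cols <- t(grDevices::col2rgb(md$color))
  expect_lt(max(abs(cols[1, ] - cols[2, ])), 20)  # months 0.1 and 11.9 match

  single <- new("SiteParameterTable", table = df[1, , drop = FALSE])
  expect_silent(plotMap(single, dest = dest))

  noGeo <- df; noGeo$latitude <- NA_real_
  expect_error(plotMap(new("SiteParameterTable", table = noGeo),
                       dest = dest), "no geo-matched sites")
  expect_error(plotMap(tab, sizeBy = "nope", dest = dest),
               "unknown parameter")
})

test_that("scatterplots render the table values verbatim", {
  cfg <- synthConfig(nSites = 5, years = 8, seed = 55)
  gen <- generatePanel(cfg)
  tab <- buildParameterTable(gen$panel, gen$geo)
  dest <- file.path(withr::local_tempdir(), "scatter.pdf")
  sd1 <- plotScatter(tab, x = "latitude", y = "peak_time", labels = TRUE,
                     dest = dest)
  df <- as.data.frame(tab)
  expect_equal(sd1$x, df$latitude)
  expect_equal(sd1$y, df$peak_time)
  expect_true(all(sd1$labelled))
  sd2 <- plotScatter(tab, sizeBy = "mean_level", dest = dest)
  expect_equal(stats::sd(sd2$markerArea / df$mean_level), 0, tolerance = 1e-9)
  expect_error(plotScatter(tab, y = "bogus", dest = dest),
               "unknown parameter.*available")
})

test_that("heat grids normalise per series and order rows by latitude", {
  cfg <- synthConfig(nSites = 3, years = 6, seed = 56,
                     latitudes = c(-10, 25, 5))
  gen <- generatePanel(cfg)
  dest <- file.path(withr::local_tempdir(), "grid.pdf")
  hg <- heatGrid(gen$panel, gen$geo, dest = dest)
  expect_identical(hg$sites, c("S02", "S03", "S01"))  # 25, 5, -10
  expect_equal(unname(apply(hg$matrix, 1, min, na.rm = TRUE)), rep(0, 3))
  expect_equal(unname(apply(hg$matrix, 1, max, na.rm = TRUE)), rep(1, 3))

  raw <- heatGrid(gen$panel, gen$geo, normalize = "none", dest = dest)
  expect_equal(unname(raw$matrix),
               unname(t(panelValues(gen$panel)[, raw$sites])))

  byCol <- heatGrid(gen$panel, orderBy = "column_order", dest = dest)
  expect_identical(byCol$sites, siteNames(gen$panel))
  expect_error(heatGrid(gen$panel, geo = NULL, orderBy = "latitude",
                        dest = dest), "requires a geolocation")
  one <- TimeSeriesPanel(panelYears(gen$panel), panelSubunits(gen$panel),
                         panelValues(gen$panel)[, 1, drop = FALSE])
  expect_error(heatGrid(one, gen$geo, dest = dest), "at least 2 series")
})
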