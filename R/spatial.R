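# Per-site parameter tables and the three geographic visual products:
# bubble map (marker size = amplitude, colour = peak timing), parameter
# scatterplot (e.g. peak timing vs latitude), and heat grid (sites x time,
# latitude-ordered). Every figure function returns the numeric data it
# rendered, so tests and downstream analyses work on data, not pixels.

#' Analyse one site of a panel
#'
#' Runs the standard per-site pipeline: trend fit, detrending, harmonic
#' fit (about the series' overall mean, so signature peak/trough values are
#' on the observed scale), seasonal signature, peak detection and the
#' linear trend coefficient. Used by [buildParameterTable()] and the
#' command-line driver.
#'
#' @param panel a [TimeSeriesPanel-class].
#' @param site site name or column index.
#' @param detrendMethod `"polynomial"`, `"spline"` or `"none"`.
#' @param trendOrder polynomial order (default 3).
#' @param stiffness spline stiffness (see [fitSplineTrend()]).
#' @param frequencies harmonic frequencies in cycles/year.
#' @param resolution signature grid resolution.
#' @return list: `site`, `trend`, `harmonics`, `signature`, `peaks`,
#'   `meanLevel`, `linearTrend`, `options` (the analysis options used; must
#'   be identical across sites when rows are assembled into one table).
#' @export
analyzeSite <- function(panel, site, detrendMethod = c("polynomial", "spline",
                                                       "none"),
                        trendOrder = 3L, stiffness = NULL,
                        frequencies = c(1, 2, 4), resolution = 1200L) {
  detrendMethod <- match.arg(detrendMethod)
  x <- panel@values[, site]
  t <- fracYears(panel)
  opts <- list(detrendMethod = detrendMethod, trendOrder = trendOrder,
               stiffness = stiffness, frequencies = frequencies,
               resolution = resolution)
  siteName <- if (is.character(site)) site else siteNames(panel)[site]
  if (all(is.na(x)))
    return(list(site = siteName, trend = NULL, harmonics = NULL,
                signature = NULL, peaks = NULL, meanLevel = NA_real_,
                linearTrend = NA_real_, options = opts, allMissing = TRUE))
  trend <- switch(detrendMethod,
    polynomial = fitPolynomialTrend(x, t, order = trendOrder),
    spline = fitSplineTrend(x, t, stiffness = stiffness),
    none = NULL)
  d <- if (is.null(trend)) x else detrend(x, trend)
  m <- mean(x, na.rm = TRUE)
  # harmonics about the overall mean: peak/trough of the signature stay on
  # the observed scale, as relative amplitude requires
  harm <- fitHarmonics(d - mean(d, na.rm = TRUE) + m, t,
                       frequencies = frequencies, P = panel@periodicity)
  sig <- seasonalSignature(harm, resolution = resolution)
  peaks <- findPeaks(sig)
  list(site = siteName, trend = trend, harmonics = harm, signature = sig,
       peaks = peaks, meanLevel = m,
       linearTrend = linearTrendCoefficient(x, t),
       options = opts, allMissing = FALSE)
}

#' Assemble the per-site parameter table
#'
#' Joins per-site analysis results with geography (via [matchPanelGeo()])
#' into the export/visualisation table: one row per matched site, one named
#' column per parameter. The column set is identical regardless of which
#' optional analyses ran (absent values are `NA`); a site whose amplitude is
#' undefined (non-positive peak) carries an explicit flag rather than being
#' silently dropped.
#'
#' @param panel a [TimeSeriesPanel-class].
#' @param geo a [GeoTable-class], or `NULL` for a geography-free table
#'   (coordinates `NA`).
#' @param results list of [analyzeSite()] results, one per site; all must
#'   have been run with identical options. Computed with defaults when
#'   `NULL`.
#' @param excess optional named numeric vector of total excess per site.
#' @param anomalyCounts optional list per site with elements `above`/`below`.
#' @return a [SiteParameterTable-class].
#' @export
buildParameterTable <- function(panel, geo = NULL, results = NULL,
                                excess = NULL, anomalyCounts = NULL) {
  sites <- siteNames(panel)
  if (is.null(results))
    results <- lapply(sites, function(s) analyzeSite(panel, s))
  names(results) <- vapply(results, `[[`, character(1), "site")
  opts <- lapply(results, `[[`, "options")
  for (o in opts[-1])
    if (!identical(o, opts[[1]]))
      stop("analysis options differ across sites; rerun with one option set")
  geoMap <- if (!is.null(geo)) matchPanelGeo(panel, geo) else
    data.frame(site = sites, latitude = NA_real_, longitude = NA_real_,
               group = NA_character_, stringsAsFactors = FALSE)
  freqs <- opts[[1]]$frequencies
  rows <- lapply(seq_len(nrow(geoMap)), function(r) {
    s <- geoMap$site[r]
    res <- results[[s]]
    row <- data.frame(site = s, latitude = geoMap$latitude[r],
                      longitude = geoMap$longitude[r], group = geoMap$group[r],
                      mean_level = res$meanLevel,
                      linear_trend = res$linearTrend,
                      stringsAsFactors = FALSE)
    for (j in seq_along(freqs)) {
      row[[sprintf("amplitude_k%g", freqs[j])]] <-
        if (is.null(res$harmonics)) NA_real_ else res$harmonics@amplitudes[j]
      row[[sprintf("phase_k%g", freqs[j])]] <-
        if (is.null(res$harmonics)) NA_real_ else res$harmonics@phases[j]
    }
    pk <- res$peaks
    row$peak_time <- if (is.null(pk) || pk@degenerate) NA_real_ else
      pk@peakTime %% 12
    row$peak_value <- if (is.null(pk)) NA_real_ else pk@peakValue
    row$trough_time <- if (is.null(pk) || pk@degenerate) NA_real_ else
      pk@troughTime %% 12
    row$trough_value <- if (is.null(pk)) NA_real_ else pk@troughValue
    row$relative_amplitude <- if (is.null(pk)) NA_real_ else pk@amplitude
    row$amplitude_flag <- if (isTRUE(res$allMissing)) "all_missing"
      else if (is.null(pk)) NA_character_ else pk@amplitudeFlag
    hasSec <- !is.null(pk) && length(pk@secondaryTime) > 0
    row$secondary_time <- if (hasSec) pk@secondaryTime else NA_real_
    row$secondary_value <- if (hasSec) pk@secondaryValue else NA_real_
    row$secondary_amplitude <- if (hasSec) pk@secondaryAmplitude else NA_real_
    row$total_excess <- if (!is.null(excess) && s %in% names(excess))
      unname(excess[s]) else NA_real_
    row$n_anomalies_above <- if (!is.null(anomalyCounts) &&
        s %in% names(anomalyCounts)) anomalyCounts[[s]]$above else NA_integer_
    row$n_anomalies_below <- if (!is.null(anomalyCounts) &&
        s %in% names(anomalyCounts)) anomalyCounts[[s]]$below else NA_integer_
    row
  })
  new("SiteParameterTable", table = do.call(rbind, rows))
}

.openDevice <- function(dest, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(dest))
  switch(ext,
    png = grDevices::png(dest, width = width, height = height, units = "in",
                         res = 150),
    pdf = grDevices::pdf(dest, width = width, height = height),
    svg = grDevices::svg(dest, width = width, height = height),
    stop("unsupported figure format '", ext, "' (use png, pdf or svg)"))
}

# cyclic 12-month colour scale: month 0 and month 12 share a colour
.cyclicMonthColor <- function(months) {
  grDevices::hsv(h = (months %% 12) / 12, s = 0.85, v = 0.9)
}

.sequentialColor <- function(v) {
  pal <- grDevices::hcl.colors(100, "Viridis")
  r <- range(v, na.rm = TRUE)
  idx <- if (diff(r) == 0) rep(50L, length(v)) else
    pmin(100L, pmax(1L, 1L + as.integer(99 * (v - r[1]) / diff(r))))
  pal[idx]
}

.isPeakTimeParam <- function(name) name %in% c("peak_time", "secondary_time",
                                               "trough_time")

#' Geographic bubble map of site parameters
#'
#' One marker per geo-matched site at its (longitude, latitude); marker
#' area is proportional to `sizeBy` and colour encodes `colorBy`, using a
#' cyclic 12-month scale for peak-time parameters (month 0 and month 12
#' share a colour) and a sequential scale otherwise.
#'
#' @param table a [SiteParameterTable-class] with coordinates.
#' @param sizeBy,colorBy parameter (column) names.
#' @param dest figure path; format by extension (png/pdf/svg).
#' @param maxArea area (pt^2) of the largest marker.
#' @return invisibly, the rendered data: data.frame with `site`, `longitude`,
#'   `latitude`, the size/colour parameters, `markerArea` and `color`.
#' @export
plotMap <- function(table, sizeBy = "relative_amplitude",
                    colorBy = "peak_time", dest, maxArea = 200) {
  df <- as.data.frame(table)
  df <- df[!is.na(df$latitude) & !is.na(df$longitude), , drop = FALSE]
  if (!nrow(df)) stop("no geo-matched sites to map")
  for (p in c(sizeBy, colorBy))
    if (!p %in% names(df))
      stop("unknown parameter '", p, "'; available: ",
           paste(names(df), collapse = ", "))
  sv <- df[[sizeBy]]
  area <- maxArea * sv / max(sv, na.rm = TRUE)  # area proportional to sizeBy
  cv <- df[[colorBy]]
  col <- if (.isPeakTimeParam(colorBy)) .cyclicMonthColor(cv)
         else .sequentialColor(cv)
  .openDevice(dest)
  on.exit(grDevices::dev.off())
  graphics::plot(df$longitude, df$latitude, pch = 21, bg = col,
                 cex = sqrt(pmax(area, 0) / pi) / 2.5,
                 xlab = "Longitude (deg)", ylab = "Latitude (deg)",
                 main = sprintf("size: %s, colour: %s", sizeBy, colorBy))
  graphics::grid()
  if (.isPeakTimeParam(colorBy)) {
    mo <- 0:11
    graphics::legend("topright", legend = month.abb,
                     pt.bg = .cyclicMonthColor(mo), pch = 21, cex = 0.6,
                     ncol = 2, title = colorBy)
  } else {
    r <- range(cv, na.rm = TRUE)
    graphics::legend("topright",
                     legend = signif(seq(r[1], r[2], length.out = 4), 3),
                     pt.bg = .sequentialColor(seq(r[1], r[2], length.out = 4)),
                     pch = 21, cex = 0.7, title = colorBy)
  }
  invisible(data.frame(site = df$site, longitude = df$longitude,
                       latitude = df$latitude, sizeValue = sv,
                       colorValue = cv, markerArea = area, color = col,
                       stringsAsFactors = FALSE))
}

#' Parameter scatterplot
#'
#' Plots one extracted parameter against another across sites — e.g. peak
#' timing against latitude to reveal a latitudinal gradient in seasonality —
#' with optional marker sizing, group colouring and per-site labels.
#'
#' @param table a [SiteParameterTable-class].
#' @param x,y parameter (column) names.
#' @param sizeBy optional parameter for marker area.
#' @param colorBy optional parameter; `"group"` (default) colours by the
#'   geo table's grouping labels.
#' @param labels draw a site-name label at each point.
#' @param dest figure path (png/pdf/svg by extension).
#' @return invisibly, the rendered data (site, x, y, size, colour).
#' @export
plotScatter <- function(table, x = "latitude", y = "peak_time", sizeBy = NULL,
                        colorBy = "group", labels = FALSE, dest) {
  df <- as.data.frame(table)
  for (p in c(x, y, sizeBy, colorBy))
    if (!is.null(p) && !p %in% names(df))
      stop("unknown parameter '", p, "'; available: ",
           paste(names(df), collapse = ", "))
  xs <- df[[x]]; ys <- df[[y]]
  area <- if (is.null(sizeBy)) rep(60, nrow(df)) else {
    v <- df[[sizeBy]]
    60 * v / max(v, na.rm = TRUE)
  }
  col <- if (identical(colorBy, "group")) {
    if (all(is.na(df$group))) rep("grey30", nrow(df)) else {
      g <- factor(df$group)
      grDevices::hcl.colors(max(2L, nlevels(g)), "Dark 3")[as.integer(g)]
    }
  } else if (.isPeakTimeParam(colorBy)) .cyclicMonthColor(df[[colorBy]])
    else .sequentialColor(df[[colorBy]])
  .openDevice(dest)
  on.exit(grDevices::dev.off())
  graphics::plot(xs, ys, pch = 21, bg = col,
                 cex = sqrt(pmax(area, 0) / pi) / 2.5, xlab = x, ylab = y)
  graphics::grid()
  if (labels) graphics::text(xs, ys, df$site, pos = 3, cex = 0.7)
  if (identical(colorBy, "group") && !all(is.na(df$group))) {
    g <- factor(df$group)
    graphics::legend("topright", legend = levels(g),
                     pt.bg = grDevices::hcl.colors(max(2L, nlevels(g)),
                                                   "Dark 3"),
                     pch = 21, cex = 0.7)
  }
  invisible(data.frame(site = df$site, x = xs, y = ys, markerArea = area,
                       color = col, labelled = labels,
                       stringsAsFactors = FALSE))
}

#' Heat grid of a multi-site panel
#'
#' Renders the panel as a matrix image: one row per series (ordered by
#' latitude, descending, or kept in column order), one column per time
#' point, cell colour from the chosen per-series normalisation. Cross-site
#' burdens often differ by orders of magnitude, so per-series min-max is the
#' default.
#'
#' @param panel a [TimeSeriesPanel-class] with at least 2 series.
#' @param geo a [GeoTable-class]; required when `orderBy = "latitude"`.
#' @param orderBy `"latitude"` (descending) or `"column_order"`.
#' @param normalize `"per_series_minmax"` (default; each non-constant row
#'   rescaled to span `[0, 1]`), `"per_series_z"`, or `"none"`.
#' @param dest figure path (png/pdf/svg by extension).
#' @return invisibly, a list: `matrix` (the numeric matrix actually
#'   rendered, rows = ordered sites), `sites` (row order), `latitudes`.
#' @export
heatGrid <- function(panel, geo = NULL,
                     orderBy = c("latitude", "column_order"),
                     normalize = c("per_series_minmax", "none",
                                   "per_series_z"),
                     dest) {
  orderBy <- match.arg(orderBy)
  normalize <- match.arg(normalize)
  if (ncol(panel@values) < 2L) stop("heat grid needs at least 2 series")
  if (orderBy == "latitude") {
    if (is.null(geo)) stop("orderBy = 'latitude' requires a geolocation table")
    gm <- matchPanelGeo(panel, geo)
    gm <- gm[order(gm$latitude, decreasing = TRUE), , drop = FALSE]
    sites <- gm$site
    lats <- gm$latitude
  } else {
    sites <- siteNames(panel)
    lats <- rep(NA_real_, length(sites))
  }
  M <- t(panel@values[, sites, drop = FALSE])
  if (normalize == "per_series_minmax") {
    M <- t(apply(M, 1, function(r) {
      rng <- range(r, na.rm = TRUE)
      if (diff(rng) == 0) r * 0 else (r - rng[1]) / diff(rng)
    }))
  } else if (normalize == "per_series_z") {
    M <- t(apply(M, 1, function(r)
      (r - mean(r, na.rm = TRUE)) / stats::sd(r, na.rm = TRUE)))
  }
  rownames(M) <- sites
  .openDevice(dest, width = 8, height = 1 + 0.5 * length(sites))
  on.exit(grDevices::dev.off())
  t <- fracYears(panel)
  graphics::image(x = t, y = seq_along(sites),
                  z = t(M[rev(seq_along(sites)), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Inferno"),
                  xlab = "Year", ylab = "", yaxt = "n")
  graphics::axis(2, at = seq_along(sites), labels = rev(sites), las = 2,
                 cex.axis = 0.7)
  invisible(list(matrix = M, sites = sites, latitudes = lats))
}
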