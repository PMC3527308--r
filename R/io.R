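# Input/output for the two file layouts the tool consumes and the parameter
# table it exports. The canonical carrier is CSV; .xlsx/.xls workbooks are
# accepted through readxl when installed (same layout, sheets carry an
# optional third dimension such as age group).

.missingTokens <- c("", "NaN", "nan", "NA", "na")

.isWorkbook <- function(source) {
  is.character(source) && grepl("\\.(xlsx|xls)$", source, ignore.case = TRUE)
}

.readRawTable <- function(source, sheet = NULL, header = TRUE) {
  if (.isWorkbook(source)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading workbooks requires the 'readxl' package; ",
           "export the sheet to CSV instead")
    df <- readxl::read_excel(source, sheet = sheet, col_names = header,
                             col_types = "text", progress = FALSE)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(source, header = header, colClasses = "character",
                          check.names = FALSE, na.strings = character(0),
                          strip.white = FALSE)
  }
  df
}

.parseNumericColumn <- function(raw, colName, issues) {
  raw <- trimws(raw)
  out <- rep(NA_real_, length(raw))
  missing <- raw %in% .missingTokens
  val <- suppressWarnings(as.numeric(raw))
  bad <- !missing & is.na(val)
  for (r in which(bad))
    issues$add("error", sprintf("row %d, column '%s'", r, colName),
               sprintf("non-numeric value '%s'", raw[r]))
  out[!missing] <- val[!missing]
  out
}

.issueCollector <- function() {
  issues <- data.frame(severity = character(0), locus = character(0),
                       message = character(0), stringsAsFactors = FALSE)
  list(
    add = function(severity, locus, message) {
      issues[nrow(issues) + 1L, ] <<- list(severity, locus, message)
    },
    get = function() issues
  )
}

# Shared scanner behind readTimeSeriesTable() and validateTimeSeriesTable():
# parses the layout, records every problem as an issue, never repairs.
.scanTimeSeries <- function(source, sheet = NULL, periodicityHint = NULL) {
  issues <- .issueCollector()
  raw <- .readRawTable(source, sheet = sheet, header = TRUE)
  panel <- NULL
  if (ncol(raw) < 3L) {
    issues$add("error", "header",
               "need at least 3 columns: year, subunit, one series")
  } else {
    years <- suppressWarnings(as.integer(trimws(raw[[1L]])))
    subunits <- suppressWarnings(as.integer(trimws(raw[[2L]])))
    if (anyNA(years))
      issues$add("error", sprintf("row %d, column 1", which(is.na(years))[1]),
                 "non-integer year")
    if (anyNA(subunits))
      issues$add("error", sprintf("row %d, column 2", which(is.na(subunits))[1]),
                 "non-integer sub-year unit")
    sites <- trimws(names(raw)[-(1:2)])
    vals <- vapply(seq_along(sites), function(j)
      .parseNumericColumn(raw[[j + 2L]], sites[j], issues),
      numeric(nrow(raw)))
    vals <- matrix(vals, nrow = nrow(raw),
                   dimnames = list(NULL, sites))
    if (!anyNA(years) && !anyNA(subunits)) {
      P <- if (is.null(periodicityHint)) max(subunits) else
        as.integer(periodicityHint)
      if (!is.null(periodicityHint) && max(subunits) > P)
        issues$add("error", "column 2",
                   sprintf("subunit %d exceeds declared periodicity %d",
                           max(subunits), P))
      if (any(subunits < 1L))
        issues$add("error",
                   sprintf("row %d, column 2", which(subunits < 1L)[1]),
                   "subunit below 1")
      if (P == 53L || any(subunits == 53L))
        issues$add("warning", "column 2",
                   "week-53 rows present; treated as ordinary within-year units")
      key <- years * as.double(P) + subunits
      if (any(diff(key) <= 0)) {
        r <- which(diff(key) <= 0)[1] + 1L
        issues$add("error", sprintf("row %d", r),
                   "rows not in ascending chronological order")
      } else {
        gap <- which(diff(key) != 1 &
                     !(diff(years) == 1L &
                       subunits[-length(subunits)] == P & subunits[-1L] == 1L))
        if (length(gap)) {
          y <- years[gap[1]]; s <- subunits[gap[1]] + 1L
          if (s > P) { y <- y + 1L; s <- 1L }
          issues$add("error", sprintf("after row %d", gap[1]),
                     sprintf("calendar gap: missing (%d, %d)", y, s))
        }
      }
      if (nCompleteYears(years, subunits, P) < 2L)
        issues$add("error", "calendar", "fewer than 2 complete years of data")
      if (!any(issues$get()$severity == "error"))
        panel <- TimeSeriesPanel(years, subunits, vals, periodicity = P,
                                 siteNames = sites,
                                 sheetLabel = if (is.null(sheet)) character(0)
                                              else as.character(sheet))
    }
  }
  df <- issues$get()
  report <- new("ValidationReport", ok = !any(df$severity == "error"),
                issues = df)
  list(panel = panel, report = report)
}

#' Read a multi-site time-series table
#'
#' Reads the standard layout: one header row, column 1 = year, column 2 =
#' within-year unit (month/week/day index), columns 3..N = one observation
#' series per site or category. Missing observations may be coded as empty
#' cells, `NaN`, `nan` or `NA`. The calendar must be contiguous and sorted in
#' ascending chronological order; the reader reports ordering and gap
#' problems as errors and never reorders or fills.
#'
#' @param source path to a CSV file (or `.xlsx`/`.xls` workbook if `readxl`
#'   is installed), or a connection (CSV only).
#' @param sheet optional workbook sheet name or index (third dimension, e.g.
#'   an age group).
#' @param periodicityHint sub-year units per year; inferred as the maximum
#'   observed subunit when `NULL`. A subunit exceeding the hint is an error.
#' @return a [TimeSeriesPanel-class].
#' @seealso [validateTimeSeriesTable()] for a non-stopping report,
#'   [writeTimeSeriesTable()] for the inverse.
#' @export
readTimeSeriesTable <- function(source, sheet = NULL, periodicityHint = NULL) {
  res <- .scanTimeSeries(source, sheet, periodicityHint)
  df <- res$report@issues
  for (i in which(df$severity == "warning"))
    warning(df$locus[i], ": ", df$message[i], call. = FALSE)
  if (!res$report@ok) {
    err <- df[df$severity == "error", , drop = FALSE]
    stop("invalid time-series table (", err$locus[1], "): ", err$message[1],
         if (nrow(err) > 1L) sprintf(" [and %d more issues]", nrow(err) - 1L),
         call. = FALSE)
  }
  res$panel
}

#' Validate a time-series table without stopping
#'
#' Runs the same checks as [readTimeSeriesTable()] but collects every issue
#' into a report instead of stopping at the first error.
#'
#' @inheritParams readTimeSeriesTable
#' @return a [ValidationReport-class].
#' @export
validateTimeSeriesTable <- function(source, sheet = NULL,
                                    periodicityHint = NULL) {
  .scanTimeSeries(source, sheet, periodicityHint)$report
}

#' Read a geolocation table
#'
#' Reads the headerless 3- or 4-column layout: site name (matching the
#' time-series header), latitude and longitude in decimal degrees, and an
#' optional fourth column with major-grouping labels (e.g. country or
#' region) used to colour maps and scatterplots.
#'
#' @param source path to a CSV file (or workbook if `readxl` is installed),
#'   or a connection (CSV only).
#' @param sheet optional workbook sheet.
#' @return a [GeoTable-class].
#' @export
readGeoTable <- function(source, sheet = NULL) {
  raw <- .readRawTable(source, sheet = sheet, header = FALSE)
  if (!ncol(raw) %in% c(3L, 4L))
    stop("geolocation table must have 3 or 4 columns (site, lat, lon[, group])")
  sites <- trimws(raw[[1L]])
  if (anyDuplicated(sites))
    stop("duplicate site name in geolocation table: ",
         sites[duplicated(sites)][1])
  lat <- suppressWarnings(as.numeric(trimws(raw[[2L]])))
  lon <- suppressWarnings(as.numeric(trimws(raw[[3L]])))
  if (anyNA(lat) || anyNA(lon))
    stop("non-numeric coordinate in geolocation table (row ",
         which(is.na(lat) | is.na(lon))[1], ")")
  if (any(abs(lat) > 90))
    stop("latitude out of range [-90, 90] (row ", which(abs(lat) > 90)[1], ")")
  if (any(abs(lon) > 180))
    stop("longitude out of range [-180, 180] (row ",
         which(abs(lon) > 180)[1], ")")
  groups <- if (ncol(raw) == 4L) trimws(raw[[4L]]) else character(0)
  GeoTable(sites, lat, lon, groups)
}

#' Match panel sites to geolocation records
#'
#' Exact string match after trimming surrounding whitespace. Panel sites
#' missing from the geolocation table are reported as a warning and excluded
#' from spatial outputs; matching no site at all is an error.
#'
#' @param panel a [TimeSeriesPanel-class].
#' @param geo a [GeoTable-class].
#' @return data.frame with one row per matched panel site: `site`,
#'   `latitude`, `longitude`, `group` (`NA` when the table has no groups),
#'   in panel column order.
#' @export
matchPanelGeo <- function(panel, geo) {
  ps <- trimws(siteNames(panel))
  gs <- trimws(geo@siteNames)
  hit <- match(ps, gs)
  if (all(is.na(hit))) stop("no sites matched between panel and geolocation table")
  if (anyNA(hit))
    warning("sites without geolocation, excluded from spatial outputs: ",
            paste(ps[is.na(hit)], collapse = ", "), call. = FALSE)
  keep <- which(!is.na(hit))
  data.frame(
    site = ps[keep],
    latitude = geo@latitudes[hit[keep]],
    longitude = geo@longitudes[hit[keep]],
    group = if (length(geo@groups)) geo@groups[hit[keep]] else NA_character_,
    stringsAsFactors = FALSE)
}

#' Write a time-series panel in the standard layout
#'
#' Inverse of [readTimeSeriesTable()]: header row, year, subunit, one column
#' per site; missing values written as `NaN`. Values are written with 17
#' significant digits, so a read-back reproduces every double bit-exactly.
#'
#' @param panel a [TimeSeriesPanel-class].
#' @param dest destination CSV path.
#' @return `dest`, invisibly.
#' @export
writeTimeSeriesTable <- function(panel, dest) {
  fmt <- function(v) ifelse(is.na(v), "NaN", sprintf("%.17g", v))
  cols <- c(list(year = panel@years, subunit = panel@subunits),
            lapply(seq_len(ncol(panel@values)),
                   function(j) fmt(panel@values[, j])))
  names(cols) <- c("year", "subunit", siteNames(panel))
  df <- data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, dest, row.names = FALSE, quote = FALSE)
  invisible(dest)
}

#' Export the per-site parameter table
#'
#' Writes one row per site and one named column per extracted parameter,
#' ready for further analysis in other tools. Numeric values are written
#' with full (15 significant digit) precision so a read-back reproduces them.
#'
#' @param table a [SiteParameterTable-class].
#' @param dest destination CSV path.
#' @return `dest`, invisibly.
#' @export
writeParameterTable <- function(table, dest) {
  df <- as.data.frame(table)
  if (!nrow(df)) stop("parameter table is empty")
  utils::write.csv(df, dest, row.names = FALSE, na = "")
  invisible(dest)
}
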