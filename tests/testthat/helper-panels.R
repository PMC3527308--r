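# In-code fixtures: small panels and their CSV renderings.

monthlyCalendar <- function(years, startYear = 2001L) {
  list(years = rep(startYear + seq_len(years) - 1L, each = 12L),
       subunits = rep(1:12, years))
}

monthlyTime <- function(years, startYear = 2001L) {
  cal <- monthlyCalendar(years, startYear)
  cal$years + (cal$subunits - 0.5) / 12
}

makeMonthlyPanel <- function(values, startYear = 2001L,
                             siteNames = paste0("S", seq_len(ncol(values)))) {
  values <- as.matrix(values)
  years <- nrow(values) / 12L
  cal <- monthlyCalendar(years, startYear)
  TimeSeriesPanel(cal$years, cal$subunits, values, periodicity = 12L,
                  siteNames = siteNames)
}

# write a minimal well-formed 2-year, 1-site monthly CSV and return its path
writeTinyCsv <- function(rows = NULL, dir = withr::local_tempdir(.local_envir =
                           parent.frame())) {
  if (is.null(rows)) {
    cal <- monthlyCalendar(2L)
    rows <- data.frame(year = cal$years, month = cal$subunits, A = 1:24)
  }
  path <- file.path(dir, "ts.csv")
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

writeGeoCsv <- function(lines, dir = withr::local_tempdir(.local_envir =
                          parent.frame())) {
  path <- file.path(dir, "geo.csv")
  writeLines(lines, path)
  path
}
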