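# Calendar helpers shared across modules. Time is measured in fractional
# years t = year + (subunit - 0.5) / P, so a January observation of monthly
# data sits at year + 1/24 (the month's midpoint), and integer harmonic
# frequencies in cycles/year line up with the calendar for any P.

fracYearAxis <- function(years, subunits, P) {
  years + (subunits - 0.5) / P
}

# number of years for which all P subunits are present
nCompleteYears <- function(years, subunits, P) {
  if (!length(years)) return(0L)
  tab <- tapply(subunits, years, function(s) length(unique(s)))
  sum(tab == P)
}

# complete years with no masked (excluded) point
nCompleteYearsUnmasked <- function(years, subunits, P, mask) {
  keep <- !mask
  if (!any(keep)) return(0L)
  nCompleteYears(years[keep], subunits[keep], P)
}

# Resolve exclusion/analysis windows to row indices. `windows` is either a
# numeric vector of whole calendar years or a list of inclusive
# c(startYear, startSubunit, endYear, endSubunit) spans.
windowIndices <- function(years, subunits, P, windows) {
  if (is.null(windows) || !length(windows)) return(integer(0))
  if (is.numeric(windows) && !is.list(windows)) {
    windows <- lapply(windows, function(y) c(y, 1, y, P))
  }
  key <- years * as.double(P) + subunits
  idx <- integer(0)
  for (w in windows) {
    if (length(w) != 4L)
      stop("each window must be c(startYear, startSubunit, endYear, endSubunit)")
    k1 <- w[1] * as.double(P) + w[2]
    k2 <- w[3] * as.double(P) + w[4]
    if (k1 > k2) stop("window start is after its end")
    if (k1 < key[1] || k2 > key[length(key)])
      stop(sprintf("window %d:%d-%d:%d lies outside the calendar span",
                   w[1], w[2], w[3], w[4]))
    idx <- c(idx, which(key >= k1 & key <= k2))
  }
  sort(unique(idx))
}

# wrap phases into [0, 2*pi); x %% (2*pi) of a tiny negative double can
# round up to 2*pi itself, which the wrap must map to 0
.wrapPhase <- function(phi) {
  p <- phi %% (2 * pi)
  p[p >= 2 * pi] <- 0
  p
}

# circular difference in months mapped to (-6, 6]
circularMonthDiff <- function(d) {
  m <- ((d + 6) %% 12) - 6
  m[m == -6] <- 6
  m
}
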