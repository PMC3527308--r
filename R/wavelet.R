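# Continuous Morlet wavelet transform (omega0 = 6), computed in the
# frequency domain with zero padding to the next power of two, following the
# standard Torrence & Compo formulation: localized power of sinusoidal
# patterns across a continuum of periods, used to see periodicities (e.g.
# annual vs biennial epidemic cycles) change over time.

#' Morlet continuous wavelet transform
#'
#' The series is mean-removed, zero-padded to the next power of two (always
#' at least doubling the length, so the transform is a linear, not circular,
#' convolution over the data span) and convolved in the frequency domain
#' with Morlet (`omega0 = 6`) daughter wavelets at scales
#' `s_j = s0 * 2^(j * dj)`, `j = 0..J`. Power is `|W|^2`; the Fourier period
#' of scale `s` is `s * 4 * pi / (omega0 + sqrt(2 + omega0^2))` (about
#' `1.033 * s`); the cone of influence is the e-folding time `sqrt(2) * s`
#' of the wavelet envelope, expressed as the longest trustworthy period per
#' time point (zero at the series ends, maximal mid-series).
#'
#' Missing values are refused rather than silently interpolated — wavelet
#' power is sensitive to imputation, so the caller decides the policy
#' (e.g. [smoothSeries()] or explicit interpolation) first.
#'
#' @param x numeric series, gap-free, length at least 16.
#' @param dt sampling interval in years (1/12 for monthly data).
#' @param s0 smallest scale (default `2 * dt`).
#' @param dj scale resolution in octaves (default 0.25).
#' @param J number of scale steps; default spans from `s0` to the series
#'   length, `floor(log2(n * dt / s0) / dj)`.
#' @return a [WaveletResult-class] with `(J + 1) x n` power matrix.
#' @examples
#' x <- cos(2 * pi * (1:384) / 12)
#' w <- morletCWT(x, dt = 1 / 12)
#' wavePeriods(w)[which.max(globalSpectrum(w))]  # ~ 1 year
#' @export
morletCWT <- function(x, dt, s0 = 2 * dt, dj = 0.25, J = NULL) {
  n <- length(x)
  if (anyNA(x))
    stop("series contains missing values; interpolate or smooth before ",
         "the wavelet transform")
  if (n < 16L) stop("series too short for a wavelet transform (need >= 16)")
  if (is.null(J)) J <- floor(log2(n * dt / s0) / dj)
  omega0 <- 6
  scales <- s0 * 2^((0:J) * dj)
  fourierFactor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))

  npad <- 2^ceiling(log2(n))
  if (npad == n) npad <- 2L * n
  xd <- c(x - mean(x), numeric(npad - n))
  fx <- stats::fft(xd)
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)

  W <- matrix(0 + 0i, nrow = J + 1L, ncol = n)
  norm0 <- pi^(-1 / 4)
  for (j in seq_len(J + 1L)) {
    s <- scales[j]
    psihat <- sqrt(2 * pi * s / dt) * norm0 *
      exp(-((s * omega - omega0)^2) / 2) * (omega > 0)
    w <- stats::fft(fx * psihat, inverse = TRUE) / npad
    W[j, ] <- w[seq_len(n)]
  }
  dist <- pmin(0:(n - 1), (n - 1):0)
  coi <- fourierFactor / sqrt(2) * dt * dist
  new("WaveletResult", power = Mod(W)^2,
      periods = fourierFactor * scales, scales = scales, coi = coi,
      time = (seq_len(n) - 0.5) * dt,
      params = list(dt = dt, s0 = s0, dj = dj, J = J, omega0 = omega0))
}

#' @rdname globalSpectrum
#' @export
setMethod("globalSpectrum", "WaveletResult", function(result) {
  vapply(seq_along(result@periods), function(j) {
    inside <- result@periods[j] <= result@coi
    if (!any(inside)) return(NA_real_)
    mean(result@power[j, inside])
  }, numeric(1))
})
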