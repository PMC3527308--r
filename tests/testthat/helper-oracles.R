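# Independent oracles, deliberately sharing no code path with the package:
# exhaustive-grid peak search with golden-section sharpening, and a direct
# time-domain Morlet convolution.

# closed-form signature for a harmonic parameter set
oracleSignatureFn <- function(meanLevel, freqs, amps, phis) {
  function(u) {
    s <- rep(meanLevel, length(u))
    for (j in seq_along(freqs))
      s <- s + amps[j] * cos(2 * pi * freqs[j] * u - phis[j])
    s
  }
}

.goldenMax <- function(f, a, b, tol = 1e-13) {
  gr <- (sqrt(5) - 1) / 2
  c <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c); fd <- f(d)
  while (b - a > tol) {
    if (fc > fd) { b <- d; d <- c; fd <- fc; c <- b - gr * (b - a); fc <- f(c) }
    else { a <- c; c <- d; fc <- fd; d <- a + gr * (b - a); fd <- f(d) }
  }
  u <- (a + b) / 2
  list(u = u %% 1, value = f(u))
}

# exhaustive grid search (gridSize points over the year) + golden sharpening
oraclePeakSearch <- function(meanLevel, freqs, amps, phis, gridSize = 1e5L) {
  f <- oracleSignatureFn(meanLevel, freqs, amps, phis)
  u <- (seq_len(gridSize) - 1) / gridSize
  v <- f(u)
  du <- 1 / gridSize
  pk <- .goldenMax(f, u[which.max(v)] - du, u[which.max(v)] + du)
  tr <- .goldenMax(function(z) -f(z), u[which.min(v)] - du,
                   u[which.min(v)] + du)
  list(peakTime = 12 * pk$u, peakValue = pk$value,
       troughTime = 12 * tr$u, troughValue = -tr$value,
       gridStepMonths = 12 / gridSize)
}

# direct time-domain Morlet (omega0 = 6) convolution: W_n(s) =
# sum_m x_m sqrt(dt/s) psi0*((m - n) dt / s), psi0(eta) =
# pi^(-1/4) exp(i omega0 eta) exp(-eta^2 / 2); x is mean-removed first
directMorletCWT <- function(x, dt, scales) {
  n <- length(x)
  xd <- x - mean(x)
  omega0 <- 6
  W <- matrix(0 + 0i, nrow = length(scales), ncol = n)
  m <- seq_len(n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    for (i in seq_len(n)) {
      eta <- (m - i) * dt / s
      psi <- pi^(-1 / 4) * exp(1i * omega0 * eta) * exp(-eta^2 / 2)
      W[j, i] <- sum(xd * sqrt(dt / s) * Conj(psi))
    }
  }
  W
}
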