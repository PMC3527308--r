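---
title: "Methods: decomposing epidemiological time series with epirhythm"
author: "epirhythm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decomposing epidemiological time series with epirhythm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epirhythm)
```

## The decomposition

`epirhythm` treats a surveillance series as trend + seasonality +
anomalies. All model fitting happens on a fractional-year axis
$t = \mathrm{year} + (\mathrm{subunit} - \tfrac12)/P$, where $P$ is the
number of sub-year units per year (12 for monthly, 52 for weekly data).
Placing each observation at the midpoint of its sub-year unit makes
integer harmonic frequencies (cycles/year) line up with the calendar for
any $P$, including 53-week years, which need no special casing.

### Trend

The default trend is an ordinary least-squares polynomial of order 3 on
*centred* time $t - t_0$, $t_0$ the midpoint of the series span. Centring
matters: with calendar years in the thousands, an uncentred cubic design
matrix has condition numbers around $10^{13}$ and coefficient recovery
fails; centred, the same fit recovers exact polynomials to $10^{-8}$ and is
invariant (to $10^{-6}$) under shifting all years by 1000. Missing
observations are dropped from the fit, and the trend is evaluated on the
full calendar so downstream code never sees gaps in the fitted component.
The order-1 slope, in series units per year, is exported per site as a
geographically comparable trend summary.

The spline alternative is a penalised **natural cubic smoothing spline**
solved with the Reinsch algorithm: minimise
$\sum_i (y_i - f(t_i))^2 + \lambda \int f''(u)^2\,du$. We implement this
directly rather than through `stats::smooth.spline` because the contract
matters at the extremes: as $\lambda \to \infty$ the solution must approach
the least-squares straight line (the penalty's null space), and the
banded Reinsch solve preserves that limit to machine precision where the
generic implementation loses it to conditioning at large $\lambda$.
$\lambda$ is exposed as the single `stiffness` parameter
(units: series-variance $\times$ years$^3$). The default picks $\lambda$ by
root-finding so the effective degrees of freedom
$\mathrm{tr}\,(I + \lambda K)^{-1}$ are about one per five years of data —
flexible enough for decadal shifts, too stiff to absorb seasonality.
`stiffness = 0` is rejected: exact interpolation removes all signal and is
not detrending.

### Seasonality

The seasonal component is a partial Fourier series fitted by OLS on
$\{1, \cos 2\pi k t, \sin 2\pi k t\}$ at $k \in \{1, 2, 4\}$ cycles/year
(12-, 6- and 3-month cycles; user-configurable), converted to amplitude
and phase: $A_k = \sqrt{a_k^2 + b_k^2}$,
$\varphi_k = \operatorname{atan2}(b_k, a_k) \bmod 2\pi$, so component $k$
is $A_k \cos(2\pi k t - \varphi_k)$. Under this convention a pure annual
harmonic peaks at month $12\varphi_1/2\pi$ with month 0 at the start of
January — phase is monotone in peak time, which keeps maps and scatterplots
interpretable.

The **seasonal signature** evaluates the harmonic model on a uniform
within-year grid (default resolution 1200, i.e. 0.01 month). Peak search
finds all local extrema on the periodic grid and then refines each with
Brent optimisation of the closed-form signature, so reported times are
accurate to roughly $10^{-8}$ months rather than one grid step. With
several harmonics the argmax has no closed form (bimodal signatures are
common and scientifically meaningful), which is why peak timing is read
from the composite signature rather than from $\varphi_1$.

Detection rules that the data alone cannot fix were set once and
documented:

- a **secondary peak** must be a local maximum separated from the primary
  by at least one month on both circular arcs, with topographic prominence
  above 5% of the primary wave height — small enough to keep genuine
  bimodality, large enough to ignore harmonic ripple;
- on an exact plateau the earliest within-year time is reported;
- a signature whose range is below $10^{-12} |\mu|$ is degenerate: peak
  times are undefined and the amplitude is 0.

**Relative amplitude** is (peak − trough)/peak on the signature built about
the series' overall mean, so peak and trough stay on the observed scale.
For a single harmonic with mean $M$ and amplitude $A$ this is exactly
$2A/(M+A)$, which the tests exploit. A non-positive peak value makes the
statistic undefined (flagged per site, never silently dropped); a negative
trough can push it above 1, which is flagged but never clipped.

Harmonic parameters are only meaningful over a reasonably stationary
period. The stationarity diagnostic reports each complete year's
within-year argmax of the detrended observations (in months) and the OLS
drift of those peak times, after mapping year-to-year differences into
$(-6, 6]$ months so a December/January alternation is not mistaken for a
six-month swing. The tool reports drift; splitting the series is the
analyst's decision.

### Baseline, prediction intervals and excess

For anomaly work the trend and harmonics are refitted **jointly** on the
non-excluded, non-missing points; the single OLS solve keeps the exclusion
contract exact (the baseline is a pure function of the points it was
fitted on, verified to $10^{-12}$). The residual scale is
$s = \sqrt{\mathrm{RSS}/(n-p)}$ with $p$ = trend order + 1 + 2 per
harmonic (the intercept counted once, inside the trend block).

The interval is a **prediction interval for a new observation**,
$\hat y \pm t_{1-\alpha/2,\,n-p}\, s$, because its use is flagging
individual observations; residuals are assumed homoscedastic Gaussian, the
simplest model consistent with monthly aggregated counts of moderate size
(no seasonal variance model is offered). Leverage is ignored: with typical
$n/p$ ratios above 50 the pointwise correction is well under 1% of the
half-width. Anomalies are *strict* bound violations — a point exactly on a
bound is not anomalous.

Excess burden over a window defaults to
$\sum \max(y - \mathrm{upper\ bound}, 0)$: burden beyond expected
variability. This under-counts by construction (the interval margin), which
the simulation tests quantify at roughly 1–2% for a concentrated event.
The signed observed-minus-baseline sum is provided as a clearly labelled
non-default alternative, since much of the excess-mortality literature
uses it.

### Wavelets

The Morlet ($\omega_0 = 6$) continuous wavelet transform follows the
standard frequency-domain algorithm: mean removal, zero padding to the
next power of two (always at least doubling, so the transform is a linear
convolution over the data span), daughter wavelets at scales
$s_j = s_0 2^{j\,dj}$ with $s_0 = 2\,dt$ and $dj = 0.25$ by default,
power $|W|^2$, Fourier period $\approx 1.033\,s$, and a cone of influence
at the $\sqrt2 s$ e-folding time. The global spectrum averages power over
time points inside the cone only.

Two numerical notes. First, the module refuses missing values rather than
interpolating: wavelet power is sensitive to imputation, so the caller
chooses the policy explicitly. Second, the discrete transform represents
the continuous one only in a mid-band of scales: at $s = 2\,dt$ the Morlet
daughter is centred beyond the sampling Nyquist frequency, and near the
padding horizon the Gaussian envelope no longer decays to negligibility
within the padded span. The equivalence test against a direct time-domain
convolution therefore compares scales from $4\,dt$ up to well inside the
padding margin, where both discretisations agree to $10^{-6}$; outside
that band each discretisation differs from the continuous transform by
terms that are properties of sampling, not implementation error.

## The synthetic generator

`synthConfig()`/`generatePanel()` produce multi-site panels with analytic
ground truth: per-site polynomial trend, shared harmonic amplitudes with a
latitude-linked peak-timing rule (peak month = intercept + slope ×
latitude; higher harmonics phase-locked so the signature translates
rigidly across sites), homoscedastic Gaussian noise, half-sine-shaped
event injections with exact totals, and missingness applied only outside
injection windows. Defaults represent a realistic mortality-like panel:
mean level 10 (e.g. deaths per 100,000 per month), amplitudes (3, 1, 0.5)
— dominant annual cycle with meaningful semi-annual structure — noise at
5% of the mean, 20 years monthly, peak month 6 at the equator with 0.1
months/degree of latitude. The true peak parameters come from an
exhaustive 100,000-point grid search sharpened by golden-section — an
oracle that shares no code path with the package's own Brent-refined peak
finder.

What the generator does **not** emulate: overdispersed or count-valued
noise, seasonally varying variance, autocorrelated residuals, reporting
artifacts (late reporting, day-of-week effects), and drifting seasonality.
Passing tests therefore demonstrate correctness of the estimators under
the stated model, not robustness to real surveillance pathologies; the
stationarity diagnostic and smoothing filters exist precisely because real
data violate these assumptions.

## Problem sizes and tolerances

The test suite fits panels of 5–50 years (one 200-year panel to check the
normal limit of the t quantile); coverage of the 95% interval is measured
on 200 replicates of 50-year monthly panels (120,000 pooled points),
excess recovery on 100 seeded replicates with a 500-unit injection over
six months, and peak-finder/oracle agreement on 100 random three-harmonic
models (times within one oracle grid step, $1.2\times10^{-4}$ months;
values within $10^{-9}$). These sizes give Monte-Carlo standard errors
comfortably below the tolerances asserted (e.g. binomial SE of pooled
coverage $\approx 0.06$ percentage points against a $\pm1.5$-point band).

## Input conventions and I/O choices

The time-series layout is one header row; year; within-year index; one
series per column — contiguous ascending calendar, missingness as `NaN`
(also accepted: empty, `nan`, `NA`). The reader **never repairs**:
reordering, gaps, non-numeric cells and short spans are reported errors
with row/column loci, and `validateTimeSeriesTable()` returns the full
issue list without stopping. CSV is canonical; `.xlsx` sheets (an optional
third dimension such as age group) are read through `readxl` when
installed. Periodicity is inferred as the maximum observed subunit unless
a hint is given; hint/data mismatch is an error. The geolocation file is
headerless — site, latitude, longitude, optional group — matched to panel
headers by exact string equality after trimming whitespace; unmatched
panel sites are warned about and excluded from spatial outputs only.

Figure functions write PNG/PDF/SVG by extension and return the numeric
data rendered (marker areas, colours, the heat-grid matrix), so tests
assert on data rather than pixels. Peak-time colour scales are cyclic —
month 0 and month 12 share a colour — which a sequential scale would get
qualitatively wrong on a map. Marker area is directly proportional to the
sized parameter. Heat grids default to per-series min-max normalisation
because cross-site burdens differ by orders of magnitude. Maps draw plain
latitude/longitude axes; no basemap is downloaded at runtime.

## Known limitations

- Harmonic and baseline fits assume fixed seasonality over the analysis
  window; use the stationarity diagnostic and split manually when it
  drifts.
- The excess estimator's upper-bound reference under-counts by the
  interval margin; the baseline reference is unbiased under the model but
  sign-cancels.
- No forecasting or extrapolation is offered, deliberately: the components
  describe the past window only.
- Irregular cadences and sub-daily data are out of scope; the calendar is
  integer year + integer subunit with fixed $P$.
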