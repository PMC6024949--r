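---
title: "Methods: PM2.5 health burden and economic-loss assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PM2.5 health burden and economic-loss assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqburden)
```

## The model

`aqburden` estimates, city by city and year by year, the health burden
attributable to annual mean PM2.5 above a baseline concentration, and its
monetary value.

**Exposure–response.** Disease and death counts are rare-event (Poisson)
outcomes, so the incidence of endpoint $i$ at concentration $C$ follows the
log-linear relative-risk form

$$E_i = E_{0i}\, e^{\beta_i (C - C_0)},$$

and the attributable (excess) cases in city $j$ with exposed population
$P_j$ are

$$HI_{ij} = P_j\, E_{0i}\left(e^{\beta_i (C - C_0)} - 1\right).$$

$C_0$ defaults to 10 µg/m³, the WHO annual guideline. $\beta_i$ (per µg/m³)
and the baseline incidence $E_{0i}$ (cases/person/yr) are meta-analysis
results and therefore **configuration inputs**, not package constants: the
packaged `endpoints_default.csv` carries illustrative values of realistic
magnitude so the pipeline runs out of the box, and real assessments should
substitute study-specific coefficients via `load_endpoint_set()`.

**Valuation.** Premature mortality is valued twice, giving an interval:

* *Upper bound — VSL benefit transfer.* A reference value of a statistical
  life $VSL_0$ (default USD 248,172) anchored at reference income
  $Income_0$ (USD 1,939) is transferred to each city by
  $VSL_j = VSL_0 (Income_j / Income_0)^{0.8}$, with income elasticity 0.8.
* *Lower bound — amended human capital.* Per-capita GDP over $t = 10$ lost
  life-years, grown at $a = 0.07$ and discounted at $r = 0.08$:
  $HCL_j = GDP_{j}\sum_{y=1}^{t} \left(\tfrac{1+a}{1+r}\right)^y$, computed
  by direct summation (and checked in tests against the geometric closed
  form).

Morbidity is valued by cost of illness: fixed per-case costs for acute
endpoints (hospitalization, treatment, lost work), and a disability-weighted
fraction of the city VSL (weight 0.055) for chronic bronchitis. Morbidity
costs are identical under both bounds; only the mortality term switches.

**Accounting.** `rollup()` enforces a non-overlapping sum: the mortality
component of the total counts only all-cause mortality — cause-specific
mortalities (cardiovascular, respiratory, lung cancer) are subsets of it and
are reported per endpoint but excluded from totals — and
`ec_total = ec_mortality + ec_morbidity` holds exactly. Likewise the
"affected population" is the sum of attributable cases over five
non-overlapping endpoints: all-cause mortality plus the four morbidity
endpoints. These are precisely the rules under which the published national
reference tables shipped with the package (`reported_health_impacts()`,
`reported_economic_losses()`) are internally consistent: their summary rows
equal the sums of their component rows.

The packaged reference tables also fix two conventions. All-cause mortality
is a *distinct* endpoint with its own coefficient, not the sum of the
cause-specific endpoints (its reported row is far from their sum).
Year-over-year reporting uses percent change relative to the earlier year,
and the "mean annual decline" is the arithmetic mean of the per-step percent
declines, *truncated* (not rounded) to one decimal — the convention under
which a 14.30%/9.41% two-step decline reports as 11.8%.

## The synthetic panel generator

No city-level concentration or socioeconomic microdata are redistributable,
so `generate_panel()` synthesises a panel with the published statistical
structure: 190 cities, 2014–2016, cross-city national mean concentrations of
62/50/47 µg/m³, and ~71% of cities in the 35–75 µg/m³ band in 2016.

Concentrations are log-normal — the simplest strictly positive, right-skewed
family that can satisfy both a mean and a band-probability target.
`solve_lognormal_params()` sets the mean analytically
($\mu = \log m - \sigma^2/2$) and root-finds $\sigma$ for the band mass; the
final-year targets identify $\sigma$, which is held constant across years
(the true cross-city dispersion is unpublished; the band target is the only
dispersion information available). Each city's log-concentration shares a
persistent city effect carrying 80% of the variance, giving the positive
across-year autocorrelation real city panels show. Income and GDP per capita
are log-normal with a Gaussian-copula correlation of 0.7 (rich cities have
both); population is log-normal and independent (no published evidence
either way, and independence keeps calibration separable). Socioeconomic
magnitudes default to Chinese city-level values of the period: median
disposable income ≈ USD 3,300/yr, median per-capita GDP ≈ USD 7,500/yr,
median city population ≈ 3 million, each with substantial log-scale spread,
growing at 7%/yr.

What the generator does *not* emulate: geography (no spatial correlation or
regional labels), within-year seasonality, station-level averaging error,
and any real joint structure between pollution and income. Tests passing on
synthetic panels therefore validate the *arithmetic and calibration* of the
pipeline, not substantive conclusions about any real city.

## Monte Carlo uncertainty

Uncertain inputs — concentration, exposure–response coefficients, per-case
costs — are described by `input_dist()` objects and propagated by
`propagate()`: each draw perturbs the inputs (by default multiplicatively),
reruns the deterministic pipeline, and the resulting total-loss distribution
is summarised per year and bound. Default families: log-normal for the
concentration factor (positive, skewed), normal truncated at zero for the
coefficient factor (meta-analysis intervals are symmetric), triangular for
the cost factor (bounded expert ranges). Quantities are independent by
default. The per-case human-capital (AHC) value is held point-valued: its
input, per-capita GDP, carries no published uncertainty, so lower-bound
mortality losses vary only through attributable cases.

Two summaries are reported, because "uncertainty" admits more than one
operational reading:

* `relative_halfwidth` — half the width of the percentile 95% CI relative to
  the mean (percentile, not normal-approximation, intervals: robust to skew);
* `uncertainty_percent()` — the share of simulated outcomes falling outside
  an acceptable error of ±5% of the expected value, the direct reading of a
  ±5% acceptability criterion. It is 0% for degenerate inputs and increases
  monotonically with every input spread.

Draws whose outputs are non-finite (e.g. a perturbed coefficient pushing the
exponent past the overflow guard) are rejected and counted; more than 1%
rejects aborts the run.

## Numerical choices and degenerate inputs

* Concentrations below $C_0$ are clamped to $C_0$ (zero attributable burden,
  flagged `clamped`), never negative "benefits": the model quantifies excess
  burden above the guideline.
* The exposure-response exponent is capped at $|\beta(C-C_0)| \le 50$ and
  fails loudly beyond it — the typical symptom of a coefficient supplied in
  the wrong units.
* Attributable cases are continuous throughout; rounding to whole cases is a
  rendering decision.
* All monetary computation is in nominal USD; the conventional reporting
  scale (hundred million USD) is applied only when formatting.
* City rankings break ties lexicographically on `city_id`, so they are
  deterministic and invariant to input row order.
* Log-normal calibration declares infeasibility (with the attainable range)
  when no dispersion reaches the requested band mass, e.g. a mean far
  outside the band.
* `annualize_concentrations()` averages the available months and flags
  city-years with fewer than 9 of 12 months, a common air-quality
  completeness rule; a city-year with no months is an error, not a silent NA.

## Problem sizes

The test-suite simulations use panels of 5–40 cities and $10^2$–$2\times10^4$
Monte Carlo draws — sizes at which every stochastic check has comfortable
sampling tolerance (3-standard-error bounds) while the whole suite runs in
well under a minute. Calibration checks that concern the full study design
(national means, band fraction) run at the full 190-city default.

## Known limitations

* The illustrative default coefficients reproduce realistic *magnitudes*,
  not any published endpoint-level estimate; endpoint-level outputs under
  the defaults are demonstrations.
* Exposure is the whole municipal resident population for every endpoint;
  no age structure (VSL without age adjustment is known to run high).
* The log-linear form is used throughout; integrated exposure–response
  (GBD-style) forms, which flatten at high concentrations, are out of scope.
* No spatial modelling: city concentration is a scalar annual mean.
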