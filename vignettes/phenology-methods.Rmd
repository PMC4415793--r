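---
title: "Temperature-driven phenology models and climatic risk indices"
author: "phenorisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-driven phenology models and climatic risk indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorisk)
```

## The modelling problem

Insects are poikilotherms: their development, survival and reproduction are
driven by ambient temperature. A temperature-driven phenology model distils a
constant-temperature cohort life-table experiment — stage-specific cohorts
reared at a ladder of constant temperatures, observed daily — into a small
set of thermal response curves, and then uses those curves to *simulate*
life tables at any temperature regime, including diurnally fluctuating field
temperatures and gridded climatologies. The package implements this chain
for a five-slot life cycle (egg, larva, pupa, adult female, adult male),
with the common cutworm *Spodoptera litura* on soybean as the built-in
reference parameterization (`slitura_phenology()`).

## The five thermal sub-models

**Development-time distribution (cumulative logit).** Within a stage at
temperature $i$, the probability of having completed by day $x$ is
$F(x) = 1/(1 + e^{-(a_i + b\ln x)})$: a log-logistic time distribution with
temperature-specific median $e^{-a_i/b}$ and one shape parameter $b$ shared
across temperatures. Fitting (`fit_dev_time_distribution()`) maximizes the
binomial likelihood of per-day cumulative completion fractions with
`stats::glm`, one intercept per temperature plus a common `log(day)` slope.
A cohort whose completions all fall on one day leaves $b$ unidentified; the
fit is then flagged and returned with the slope capped at 60 (an essentially
deterministic duration at daily resolution) and the median at the observed
day.

**Development rate (modified Sharpe–DeMichele).** Mean development (and
adult senescence) rate versus absolute temperature,

$$r(T) = \frac{p \, (T/T_o) \exp\left[\tfrac{\Delta H_a}{R}(1/T_o - 1/T)\right]}
       {1 + \exp\left[\tfrac{\Delta H_h}{R}(1/T_h - 1/T)\right]},$$

the four-parameter variant that keeps high-temperature enzyme inactivation
only ($R = 1.987$ cal K$^{-1}$ mol$^{-1}$). Two numerical facts shape the
fitter (`fit_development_rate()`). First, $p$, $T_o$ and $\Delta H_a$ enter
the curve only through $c = p\,e^{\Delta H_a/(R T_o)}/T_o$, so $T_o$ is a
reporting convention rather than a free parameter: after fitting we set
$T_o$ to the fitted curve's argmax (capped just below $T_h$) and recompute
$p$ in log space so the curve is unchanged. Second, the likelihood surface
has a long ridge, so we run Levenberg–Marquardt (`minpack.lm::nls.lm`, which
tolerates a rank-deficient Jacobian at the optimum) from a grid of starts:
enthalpies on a log grid $10^3$–$10^6$ cal/mol plus an Arrhenius seed from
the regression of $\log r$ on $1/T$, and $T_o$/$T_h$ seeded from the fastest
observed rate and the hottest tested temperature. When the observed rates
never decline the inactivation branch is unidentifiable; such fits are
flagged `Th_at_bound` and should only be evaluated inside the tested range.
This is the normal situation for adult senescence rates, which rise
monotonically over any realistic range.

**Stage mortality (Wang).** Total immature mortality
$m(T) = 1 - \exp\{-H[1 + e^{-(T-T_{opt})/B}][1 + e^{-(T_{opt}-T)/B}]\}$, a
symmetric U around the survival optimum $T_{opt}$ with spread $B$ (°C) and
intensity $H$; the minimum equals $1 - e^{-4H}$ exactly. Fitted by bounded
Levenberg–Marquardt with $H \ge 0$; uniformly zero mortalities return the
boundary solution $H = 0$ directly.

**Total fecundity.** Lifetime eggs per female,
$f(T) = \exp(a + bT + cT^2)$, peaking at $-b/(2c)$ when $c<0$ (26.5 °C for
the reference coefficients $-13.30, 1.59, -0.03$). A literal bounded form
$1 - e^{-(aT + bT^2 + cT^3)}$ is retained behind the `form` switch for
completeness, but being confined to $[0,1)$ it can only serve as a
normalized index, never an egg count, so the exponential quadratic is the
default. The fit is ordinary least squares of $\log f$ on $T, T^2$ —
exact ML under multiplicative error — polished on the raw scale.

**Age-specific oviposition (Gamma).** The cumulative fraction of lifetime
eggs laid by normalized age $X$ (adult age in days over mean adult survival
time) is the Gamma CDF with shape $a$ and *rate* $b$. The rate (not scale)
convention is pinned by the reference fit (shape 5.99, rate 10.32) whose
median normalized age is 0.548 — matching the published value 0.55, whereas
the scale reading would put the median near 58, a physical impossibility.

`select_model()` ranks alternative fits by AIC with an $R^2$ tie-break and
never drops candidates.

## From daily weather to sub-daily temperatures

Daily minima and maxima are expanded to 96 fifteen-minute steps by the
cosine half-day rule: within a half day,
$T_i = \tfrac{Max-Min}{2}\cos(\pi(i-0.5)/48) + \tfrac{Min+Max}{2}$,
$i = 1..48$, sweeping max to min over one half cosine period. The first
half day uses the day's own minimum and maximum; the second repeats the
sweep toward the *next* day's minimum (the final day reuses its own). The
phase of the second half-day is a judgement call — the rule as stated fixes
only which minimum is used — but rate summation integrates over the day's
multiset of temperatures, so downstream results are insensitive to the
within-day ordering. Monthly climatologies are expanded to 365-day series
by linear interpolation between month-midpoint anchors (December wrapping
to January); anchor-day values equal the monthly inputs exactly, and
monthly means track the anchors to within about 0.2 °C at realistic
seasonal amplitudes (the interpolation error grows with the curvature of
the annual cycle).

## The life-table simulator

The stochastic engine (`simulate_life_table()`) is a cohort-updating /
rate-summation reconstruction. The exact internals of the established
desktop tools in this family are not published, so the package documents
its own: each individual draws, per stage, a completion threshold $\theta$
from the log-logistic form of the logit distribution (median 1, shape $b$),
accumulates physiological age by $r(T)\,dt$ — with $r$ averaged over the 96
sub-daily steps under fluctuating temperatures — and moults when the
accumulator crosses $\theta$. At constant temperature this reproduces the
fitted development-time distribution exactly on the daily grid. Stage
mortality is applied as a daily hazard $h = 1 - (1-m(T))^{1/D(T)}$ with
$D(T) = 1/r(T)$ the median stage duration (capped at 365 d so extreme
temperatures still resolve); this conversion preserves the stage-level
total $m(T)$ at constant temperature. Adults age by their senescence
curves; females lay $f(T) \times [G(X_{new}) - G(X_{old})]$ eggs per day
(Poisson), the Gamma increment taken over senescence physiological age, and
eggs split into daughters binomially with the sex ratio. Stage processing
runs adults first and then pupa → egg, so nothing advances twice in one
step.

Survivorship `lx` tracks the whole founding cohort (both sexes); `mx` is
daughters laid on day $x$ per cohort member alive, so
$R_o = \sum l_x m_x$ equals total daughters per founding egg exactly — the
standard two-sex approximation for this tool family. The six parameters
follow: $GRR = \sum m_x$, $r_m$ solves the Lotka–Euler equation
$\sum e^{-r_m x} l_x m_x = 1$ by bisection on $[-1, 2]$ d$^{-1}$ (expanded
to $[-5,5]$ if needed, tolerance $10^{-8}$), $\lambda = e^{r_m}$,
$T = \ln R_o / r_m$, $D_t = \ln 2 / r_m$. Replicates with no reproduction
report $R_o = 0$ and flagged `NA` rates — never an error — so temperature
sweeps across lethal extremes complete.

`deterministic_life_table()` is an independent oracle: it propagates
expected stage-entry distributions by direct convolution of the
discretized duration laws, hazards and the Gamma schedule, with no shared
code path through the stochastic stepping. The test suite requires the
stochastic means to sit within three standard errors of the oracle.

A single integer seed drives per-replicate independent streams and is
recorded in every result.

## Risk indices and mapping

For each Julian day the mean of the sub-daily profile gives the day's
temperature $\bar T_x$. A stage is *non-survivable* on a day when its Wang
mortality at $\bar T_x$ exceeds a configurable cutoff (default 0.99) or its
development rate vanishes at every sub-daily step; the cutoff reproduces
lethality at the reference study's extremes without introducing new
parameters, and is deliberately exposed in `risk_config()` because the
original rule is not published. Then:

* $ERI = \prod_s (1 - x_s)$ over the three immature stages, $x_s$ the
  fraction of non-survivable days — 1 means year-round survivable;
* $GI = \operatorname{mean}_x(365/T_x)$, the mean annualized generation
  count, with $T_x$ the quadratic mean-generation-time response evaluated
  at $\bar T_x$ (clipped to its fitted range, since a quadratic has no
  meaning beyond the data);
* $AI = \sum_x \log_{10}\lambda_x$ with $\lambda_x = e^{r_m(\bar T_x)}$
  from the quadratic $r_m$ response. Days with $r_m < 0$ contribute
  negative terms rather than being floored: AI is a log-scale potential and
  flooring would destroy its additivity over sub-periods.

The quadratic responses $L(T) = a + bT + cT^2$ are fitted by least squares
to the simulated parameters across constant temperatures
(`fit_parameter_response()`); evaluating a full cohort simulation at every
grid cell and Julian day would be prohibitive and is not what the response
surface route requires. `grid_risk()` applies `location_risk()` per cell of
a 12-month min/max climatology stack, propagating nodata; `change_map()`
subtracts two climatologies; `apply_mask()` restricts to a 0/1 raster mask
(e.g. a rasterized cropland layer). Grids are carried in memory as plain
matrices with geometry metadata and read/written as ESRI ASCII grids — a
plain-text single-band raster format that keeps the whole pipeline
text-only and dependency-light; polygon masks and projected raster formats
are out of scope.

## The synthetic-data generator

`generate_cohort()` emits cohort observations with exactly the assumed
structure: Bernoulli survival from the Wang curve, development times by
inverse-CDF sampling from the logit law *rounded up to whole days* (the
field records daily observations; the fitters are tested explicitly against
this discretization, which is benign because the empirical day-grid CDF
still equals the continuous CDF at integer days), adult lifespans from the
adult logit laws, Poisson (or negative-binomial, `dispersion > 1`) lifetime
egg totals allocated across days by Gamma-schedule increments. Defaults
mirror a typical rearing design: 400 eggs, 200 larvae, 100 pupae and 30
adult pairs per temperature at 15–38 °C. `generate_weather()` produces a
sinusoidal annual cycle with Gaussian noise (defaults: mean 25 °C,
amplitude 8 °C, diurnal range 11 °C, noise 1.5 °C — a semi-arid Indian
station year); `generate_climate_raster()` adds a south–north gradient over
a grid. What the generators do *not* emulate: humidity and photoperiod
effects, host-plant differences, inter-individual frailty correlations, and
autocorrelated weather — so green tests certify the estimation machinery,
not the biology of any particular field population.

## Problem sizes and numerical choices

The test suite simulates founding cohorts of 100–1000 eggs with 10–50
replicates per temperature and fits recovery suites of 60 Monte-Carlo
replicates at the rearing-design cohort sizes; the deterministic oracle
uses an adaptive horizon (six times the summed median stage durations,
capped at 5000 days). Key tolerances: Lotka–Euler bisection $10^{-8}$;
demographic identities hold to $10^{-6}$ in every emitted result; fitted
mortality is clamped to $[0,1]$ after evaluation and $H \ge 0$ is enforced
in fitting. Developmental threshold temperatures (the points where the
fitted rate falls to a small fraction of its maximum) are deliberately not
exposed as headline outputs: the extraction rule behind published threshold
values is not stated, so any reimplementation would be a guess.

## Known limitations

* The engine models temperature only: no density dependence, migration,
  diapause, natural enemies, humidity or host-plant effects.
* Adult senescence curves for the reference parameterization are refit from
  published mean senescence times (the original curve parameters are not
  available); their inactivation branch is unidentifiable and flagged.
* The reference sex ratio is fixed at 0.5 per the study design; the class
  supports temperature-specific ratios when data exist.
* Quadratic parameter responses are clipped, not extrapolated; risk maps
  outside the fitted 15–38 °C range reflect boundary values.
* ESRI ASCII grids carry no coordinate reference system; the `crs` tag is
  free text and no reprojection or resampling is attempted.
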