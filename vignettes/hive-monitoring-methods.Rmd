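---
title: "Methods: decomposing continuous hive data and cage survivorship"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decomposing continuous hive data and cage survivorship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hivebeat)
```

## The measurement problem

A honey bee colony on an electronic scale produces a mass trace shaped by
several processes on different time scales: comb and stores accumulate over
weeks (trend); foragers leave in the morning and return by dusk, carrying a
within-day mass deficit of order 0.1–2 kg (diurnal cycle); syrup feeds add
step changes that decay as bees evaporate the water fraction; and robbing —
foreign foragers stripping stored honey — collapses hive mass within hours.
Internal temperature behaves analogously: a brood-rearing colony regulates
the nest near 34–35 °C with small daily variation, while a broodless or
weakened colony tracks ambient with large daily swings.

`hivebeat` separates these scales and turns each into a response variable
suitable for treatment comparison in dose–response field trials.

## Trend and residual

The trend at a sample is the mean of all samples within ±12.5 h (a 25-h
centred running average); the residual is raw minus trend. Two numerical
choices matter:

* **Window length 25 h, not 24 h.** An averaging window equal to the
  diurnal period would annihilate the daily cycle only in the ideal case
  and is maximally sensitive to phase alignment; the extra hour
  deliberately detunes the window from the cycle. A side effect is that the
  trend retains a small *negative* correlation with the 24-h component, so
  detrending multiplies a 24-h sinusoid's amplitude by a gain slightly
  above 1. On a 15-min grid the gain has the closed form
  `1 − sin(Nθ)/(N sin θ)` with `N = 101` window samples and
  `θ = π·0.25/24`, i.e. ≈ 1.0493 (`detrend_gain()`). All amplitude-recovery
  tolerances in the test suite are stated against this analytic
  expectation, not against the injected amplitude itself.
* **Symmetric closed window.** Both boundary samples (exactly ±12.5 h on a
  15-min grid) are included. A half-open convention would drop one boundary
  sample and make the window asymmetric, introducing a phase lag and
  breaking the exactness of the centred mean on linear ramps; symmetry
  keeps the trend at zero phase lag, which matters because amplitudes are
  compared across treatment groups by calendar day. A consequence worth
  knowing: the detrender's response to a single-sample impulse spans
  exactly one window length (25 h), which the acceptance script measures
  directly.

Windows that overlap the series boundary or an annotated gap (any
inter-sample interval > 1.5 × the nominal step) are masked, never filled —
interpolation would manufacture signal exactly where the sine fits are most
sensitive. Timestamps are naive local wall-clock with no DST handling; the
loggers record local time, and no clock-drift correction between scale and
temperature loggers is attempted (none is identifiable from the data).

## Daily amplitudes

A fixed-period 24-h sine plus intercept is fitted by linear least squares to
3-day windows of residuals, stepped by one day, each fit assigned to the
window's centre day. The period is a configuration knob but is never
fitted: the scientific quantity is the amplitude of the daily cycle, and
letting the period float would conflate frequency drift with amplitude
change. Time for the phase origin is hours since the window-start midnight,
so phases are comparable across windows (a one-day step shifts the origin by
exactly one period).

A window is fitted only if at least 50% of its nominal samples are present
and valid — tolerant enough to keep windows adjacent to logger dropouts
(which lose the 12.5-h detrend margin on one side) while rejecting windows
that overlap a full-day gap. With the default spans, a 10-day gap-free
series yields 8 records (centre days 2–9), and a 1-day interior gap removes
exactly the three windows that touch it.

For repeated-measures analyses the daily series is thinned to every 5th day
(`thin_for_rm()`), anchored at the first available centre day, so that kept
3-day windows are separated by two clear days and share no samples; steps
below `span + 1` are refused unless explicitly overridden.

## Behavioural events

* **Nectar flow**: a maximal run of consecutive days, starting and ending
  on a rising day, with rising-day fraction ≥ 0.8 and positive cumulative
  gain, lasting *strictly* more than 7 days. "Largely monotonic" is
  operationalised as the 0.8 fraction (configurable): it tolerates isolated
  rainy or robbed days without abandoning the visual definition of a
  sustained flow.
* **Robbing**: the union of a daily screen (net midnight-to-midnight loss
  strictly greater than 1.5 kg — evaporation of fed syrup loses weight, but
  not that much) and a rapid screen (peak-to-trough drop ≥ 2 kg within
  strictly less than 6 h). The rapid screen uses peak-to-trough rather than
  window endpoints because robbing signatures are monotone collapses and
  endpoints are noisy. Overlapping flags merge into one event carrying both
  triggers. Feeding days can optionally be excluded from the daily screen
  (off by default) when a feeding schedule is supplied.

Both strict inequalities are boundary-tested: a 7-day rising run and an
exactly-1.5 kg loss day are, by construction, not events.

## Cage survivorship

Daily death counts are interval-censored in truth; following the standard
lifetime-regression usage they are expanded to exact times at day midpoints
(`d − 0.5`), with removals (five to eight live bees sampled at weeks 4 and
6, plus termination at day 50) right-censored at their day. The Weibull AFT
model `log T = μ + σW` is fitted by maximum likelihood via
`survival::survreg`; percentiles follow in closed form,
`t_p = exp(μ + σ log(−log(1 − p)))`, and the test suite checks the fit
against an independent direct maximisation of the censored log-likelihood.

The shape response variable is "30th percentile minus 40th percentile".
Taken on mortality (CDF) percentiles this is negative for any distribution;
on survivorship percentiles (times at which 30% and 40% remain alive) it is
positive. The field usage is ambiguous, so `shape_stat()` emits either
convention, with both underlying percentile times, and asserts neither as
canonical.

Bee-days use the convention that a bee recorded dead at the day-`d` check
lived through day `d` (deaths are discovered at daily checks, so the bee
was alive for most of its recorded death day); `death_day_weight` ∈
{0, 0.5, 1} makes the convention auditable, and the per-bee enumeration
oracle in the tests implements each convention independently. Consumption
is grams consumed × 1000 / bee-days, in mg/bee/day.

## Treatment comparison

Field inference in these trials is period-wise: responses are summarised
per hive within pre-/during-/post-treatment windows and compared across
groups with pre-treatment values (or adult bee mass) as covariates. The
full multivariate repeated-measures machinery is intentionally not
reproduced — with four hives per group the substantive inferences are
period-wise contrasts, and exact equivalence to any particular mixed-model
covariance structure is not identifiable from published summaries. The
simplification is stamped into `rm_group_time()` output metadata. Periods
must not overlap, and a period leaving any group with fewer than two hives
is skipped with the reason recorded.

Within a period, `ancova()` fits `response ~ covariate + group`, tests the
group factor by F (sequential, group after covariate), and reports
covariate-adjusted means with all pairwise contrasts Bonferroni-adjusted
(`p_adj = min(1, m·p_raw)`, `m` = number of pairs; Bonferroni, not Tukey,
to match the field convention). The compact letter display uses the
insert-and-absorb algorithm; a property test verifies that groups sharing
no letter are exactly the significant pairs. α defaults to 0.05 and is
configurable. Frame spaces (half-integer ordinal scores) go through
`kruskal_wallis_groups()`, with the fully tied case defined as H = 0,
p = 1. Brood areas measured photographically and by hexagon grid are
tagged by method and never pooled across methods.

## The synthetic generator

`gen_weight_series()` builds mass as base + piecewise-linear trend +
diurnal deficit + feeding steps + robbing ramps + uniform noise
(±20 g by default, matching the nominal precision of hive-scale loggers;
uniform rather than Gaussian because the error budget is
quantisation-like). The diurnal signature is a daylight (06:00–18:00)
half-sine deficit of depth `2A`: its 24-h Fourier fundamental has amplitude
exactly `A`, and the half-sine's harmonics are orthogonal to the sine fit
over full windows, so the expected fitted amplitude is `A` times the
detrend gain — recorded in the ground truth as
`expected_detrended_amplitude`. The noise substream depends only on the
scenario seed, so scenarios differing only in injected events are paired
sample-for-sample (the basis of the injection–recall experiments).

`gen_temp_series()` is setpoint (34.5 °C) + regime-dependent daily
sinusoid + optional ambient coupling + ±0.06 °C noise;
`gen_cage_trial()` draws per-bee Weibull times, bins them to daily counts
(death during `(d−1, d]` is recorded at the day-`d` check), applies the
scheduled censoring, and sets weekly syrup consumption to the true rate
times the interval's bee-days, so the consumption estimator round-trips
exactly at zero noise.

What the generator does *not* emulate: weather-driven nectar variability,
multi-harmonic and seasonally varying diurnal waveforms, swarming and
absconding, sensor drift, and correlated noise. Passing the recovery and
round-trip suites therefore demonstrates correctness of the estimators
under the stated model, not robustness to every feature of real field
data.

## Problem sizes and tolerances

The validation suite uses desk-scale simulation sizes chosen to keep
sampling error well inside the asserted bounds: 100 random series for the
running-average brute-force equivalence and 100 random trials for the
bee-day enumeration; 50 synthetic hives per amplitude level (0.1, 0.5,
2.0 kg) with the 5% median-recovery bound stated against the analytic
expectation; 200 replicates for the Weibull μ coverage check (accepting
92–98% for a nominal 95% Wald interval); 1000 null simulations for the
ANCOVA type-I rate (accepting 3.5–6.5%); and 100 paired traces for the
robbing injection–recall experiment (recall 1.0, false positives 0, with
injections placed within a single calendar day so the daily screen is a
guaranteed backstop for slow collapses near the rapid-screen boundary).

## Known limitations

* No DST or clock-drift handling; timestamps are trusted as local time.
* The interval-censored nature of daily death counts is approximated by
  midpoint placement, not an interval likelihood (extension point).
* Adult-mass estimation depends on which frame tare is subtracted; both
  modes (`start-tare-only`, `current-frames`) are provided and flagged,
  and negative estimates are floored at zero with a flag rather than
  rejected, since comb growth can exceed the tare assumptions.
* Spectral alternatives (FFT, Lomb–Scargle) and multi-harmonic fits are
  out of scope; only the 24-h component is asserted recoverable.
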