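# hivebeat

Colony-level analytics for continuous honey bee hive monitoring and cage
bioassays, built for ecotoxicology field trials in which colonies are fed
sublethal pesticide doses (e.g. imidacloprid at 0/5/20/100 ppb in sugar
syrup) and monitored with hive scales, internal temperature sensors,
periodic inspections and caged-bee survival assays.

The package is aimed at researchers who have continuous hive-scale data and
want the standard response variables of that literature — daily weight and
temperature amplitudes, behavioural event classifications, survivorship
percentiles, per-bee-day consumption — together with the treatment-comparison
statistics, and a synthetic-data generator with known ground truth for
validating every step.

## What it computes

**Signal decomposition.** A hive-weight (15-min) or internal-temperature
(30-min) series *y(t)* is split into a trend — the centred 25-h running
average *m(t)* — and within-day residuals *r(t) = y(t) − m(t)*. Daily
variability is the amplitude *A* of a fixed-period 24-h sine fitted by least
squares to 3-day windows of residuals stepped one day at a time:

    r(t) ≈ a·sin(2πt/24) + b·cos(2πt/24) + c,   A = √(a² + b²)

Weight amplitude indexes forager mass flux (flight activity); temperature
amplitude indexes thermoregulation (low = active brood-nest temperature
control). Amplitude series are thinned to every 5th day for repeated-measures
use so consecutive 3-day windows share no samples.

**Event detection.** Nectar flows are maximal runs of largely monotonic
daily gain (fraction of rising days ≥ 0.8) lasting strictly more than 7
days. Robbing is flagged by either a daily net loss strictly exceeding
1.5 kg/day or a peak-to-trough collapse of ≥ 2 kg within less than 6 h;
overlapping flags merge into single events.

**Cage survivorship.** Daily death counts with scheduled censoring (live
bees sampled at days 28 and 42, termination at day 50) are expanded to
per-bee records and fitted with a right-censored Weibull accelerated
failure time model, log *T* = μ + σW. Response variables are the 30th and
50th percentiles and the shape statistic (30th − 40th percentile), plus
syrup consumption in mg per bee-day (one bee-day = one bee alive one day).

**Colony metrics and statistics.** Hexagon-grid brood area (23.4 cm² per
cell), Varroa fall (mites/day) and density (mites/bee), feed and
unconsumed-syrup accounting, µM→ppm dose conversion, and a
treatment-comparison layer: ANCOVA with pre-treatment covariates,
Bonferroni-adjusted pairwise contrasts with compact letter displays,
Kruskal–Wallis tests, and period-wise group comparisons.

## Worked example

```r
library(hivebeat)

# a 10-day synthetic hive: 0.5 kg daily amplitude, ±20 g noise,
# one robbing collapse (2.5 kg over 4 h on day 6)
sc <- hive_scenario(seed = 42, days = 10, diurnal_amplitude_kg = 0.5,
                    robbing = data.frame(day = 6, start_hour = 10,
                                         duration_h = 4, loss_kg = 2.5))
g <- gen_weight_series(sc)
g$series
#> <weight series> hive synthetic: 960 samples, 2014-07-01 to 2014-07-10 23:45:00, step 15 min, 0 gap(s)

amps <- amplitude_series(detrend(g$series))
head(amps, 3)
#>     hive_id        day   kind amplitude    phase        offset      rmse   n
#> 1 synthetic 2014-07-02 weight 0.5223687 1.605383 -0.0008347523 0.1465985 238
#> 2 synthetic 2014-07-03 weight 0.5236917 1.572569 -0.0001178211 0.1472618 288
#> 3 synthetic 2014-07-04 weight 0.5259472 1.571983  0.0006551454 0.1468258 288
median(amps$amplitude)                  # 0.5248194
g$truth$expected_detrended_amplitude    # 0.5246466 (analytic: 0.5 × 1.0493)

detect_robbing(g$series)
#>     hive_id      start        end  loss_kg loss_window_h               trigger
#> 1 synthetic 2014-07-06 2014-07-07 2.787895            24 daily_rate+rapid_drop
```

The recovered median amplitude matches the generator's analytic expectation
(the injected 0.5 kg fundamental times the 1.049 transfer gain of the 25-h
detrend); the injected collapse is found once, by both screens.

```r
cage <- gen_cage_trial(cage_scenario(seed = 42, treatments = data.frame(
  ppb = c(0, 100), mu = c(log(42), log(38)), sigma = 0.3,
  consumption_mg_bee_day = c(22.6, 18.5)), n_cages = 2))
f <- fit_weibull(expand_to_individuals(cage$trials[[1]], final_day = 50))
f
#> <Weibull AFT fit> n = 100 (76 deaths): mu = 3.7547 (SE 0.0288), sigma = 0.2509 (SE 0.0240)
#>   percentiles (d): p30 = 32.98, p40 = 36.09, p50 = 38.97
shape_stat(f)$value                     # -3.110782 (p30 − p40, CDF convention)
consumption_per_bee(cage$trials[[1]], c(1, 7))   # 22.6 mg/bee/day, exact round trip
```

Here μ̂ = 3.75 (true log 42 = 3.74) and σ̂ = 0.25 (true 0.30) from one
100-bee cage under the standard censoring pattern; consumption recovers the
generated rate exactly.

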