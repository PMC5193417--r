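# Cage-bioassay analytics: censored Weibull survivorship, percentile and
# shape response variables, and per-bee-day consumption rates.
#
# Cages start with n0 bees (100 in the trials this package targets); dead
# bees are counted daily, live bees are removed (censored) at scheduled
# samplings, and all survivors are censored at termination. Survivorship is
# modelled as a Weibull accelerated-failure-time (AFT) fit:
# log T = mu + sigma * W with W standard minimum-extreme-value, so
# percentile(p) = exp(mu + sigma * log(-log(1 - p))).

#' Construct a validated cage trial
#'
#' @param cage_id Cage identifier.
#' @param treatment_ppb Imidacloprid concentration of the syrup fed, ppb.
#' @param n0 Initial number of bees (default 100).
#' @param deaths Data.frame `day, n`: dead bees counted at the daily check.
#' @param censored Data.frame `day, n`: live bees removed (sampling,
#'   termination).
#' @param syrup Optional data.frame `start_day, end_day, grams`: syrup
#'   consumed per weighing interval (intervals must not overlap).
#' @param water_total Optional total water consumed, grams.
#' @return A list of class `hb_cage_trial`.
#' @export
cage_trial <- function(cage_id, treatment_ppb, n0 = 100,
                       deaths = data.frame(day = integer(), n = integer()),
                       censored = data.frame(day = integer(), n = integer()),
                       syrup = NULL, water_total = NA_real_) {
  stopifnot(n0 >= 1, all(deaths$n >= 0), all(censored$n >= 0),
            all(deaths$day >= 1), all(censored$day >= 1))
  if (sum(deaths$n) + sum(censored$n) > n0)
    stopf("cage %s: deaths (%d) + censored (%d) exceed n0 = %d",
          cage_id, sum(deaths$n), sum(censored$n), n0)
  if (!is.null(syrup) && nrow(syrup) > 1L) {
    s <- syrup[order(syrup$start_day), ]
    if (any(s$start_day[-1] <= s$end_day[-nrow(s)]))
      stopf("cage %s: syrup weighing intervals overlap", cage_id)
  }
  structure(list(cage_id = as.character(cage_id), treatment_ppb = treatment_ppb,
                 n0 = n0, deaths = deaths, censored = censored,
                 syrup = syrup, water_total = water_total),
            class = "hb_cage_trial")
}

#' @export
print.hb_cage_trial <- function(x, ...) {
  cat(sprintf("<cage trial> %s (%g ppb): n0 = %d, %d deaths, %d censored\n",
              x$cage_id, x$treatment_ppb, x$n0, sum(x$deaths$n), sum(x$censored$n)))
  invisible(x)
}

#' Expand a cage trial to per-bee survival records
#'
#' One record per bee: deaths at their recorded day (by default placed at
#' the day midpoint, `day - 0.5`, since daily counts are interval-censored
#' in truth and the midpoint is the conventional exact-time placement),
#' censored bees at their removal day, and any remaining bees censored at
#' `final_day` (defaults to the last recorded day). The expansion conserves
#' `n0` exactly.
#'
#' @param trial An [cage_trial()] object.
#' @param final_day Termination day for remaining survivors; `NULL` for the
#'   last day seen in the records.
#' @param death_time `"midpoint"` (default) places a day-`d` death at
#'   `d - 0.5`; `"day"` places it at `d`.
#' @return Data.frame `time, status` (1 = death, 0 = censored), `n0` rows.
#' @export
expand_to_individuals <- function(trial, final_day = NULL,
                                  death_time = c("midpoint", "day")) {
  stopifnot(inherits(trial, "hb_cage_trial"))
  death_time <- match.arg(death_time)
  final_day <- final_day %||%
    max(c(trial$deaths$day, trial$censored$day, 1))
  dt <- rep(trial$deaths$day, trial$deaths$n)
  if (death_time == "midpoint") dt <- dt - 0.5
  ct <- rep(trial$censored$day, trial$censored$n)
  n_left <- trial$n0 - length(dt) - length(ct)
  rec <- data.frame(
    time = c(dt, ct, rep(final_day, n_left)),
    status = c(rep(1L, length(dt)), rep(0L, length(ct) + n_left)))
  stopifnot(nrow(rec) == trial$n0)
  rec
}

#' Fit a right-censored Weibull AFT survivorship model
#'
#' Maximum-likelihood accelerated-failure-time fit (via
#' [survival::survreg()] with `dist = "weibull"`, the analogue of the
#' classical lifetime-regression procedure): `log T = mu + sigma * W`, `W`
#' standard minimum extreme value. Standard errors come from the observed
#' information matrix. Requires at least two distinct death times; with no
#' (or degenerate) deaths a no-fit result carrying the reason is returned.
#'
#' @param records Data.frame `time, status` as from
#'   [expand_to_individuals()].
#' @return A list of class `hb_weibull_fit`: `mu`, `sigma`, `se_mu`,
#'   `se_sigma` (delta method from the log-scale SE), `loglik`, `n`,
#'   `n_events`, `percentiles` (p30/p40/p50, days), `fit` (the underlying
#'   survreg object) -- or an `hb_nofit`.
#' @export
fit_weibull <- function(records) {
  stopifnot(all(c("time", "status") %in% names(records)))
  ev <- records$time[records$status == 1]
  if (length(unique(ev)) < 2L)
    return(structure(
      list(reason = sprintf("%d distinct death times (need >= 2)",
                            length(unique(ev)))), class = "hb_nofit"))
  sf <- survival::survreg(survival::Surv(time, status) ~ 1, data = records,
                          dist = "weibull")
  mu <- unname(coef(sf)[1])
  sigma <- sf$scale
  V <- vcov(sf)  # (intercept, log(scale))
  se_mu <- sqrt(V[1, 1])
  se_log_sigma <- sqrt(V[2, 2])
  ps <- c(p30 = 0.30, p40 = 0.40, p50 = 0.50)
  pct <- vapply(ps, function(p) exp(mu + sigma * log(-log(1 - p))), numeric(1))
  structure(list(mu = mu, sigma = sigma, se_mu = se_mu,
                 se_sigma = sigma * se_log_sigma,
                 loglik = sf$loglik[1], n = nrow(records),
                 n_events = sum(records$status == 1),
                 percentiles = pct, fit = sf),
            class = "hb_weibull_fit")
}

#' @export
print.hb_weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<Weibull AFT fit> n = %d (%d deaths): mu = %.4f (SE %.4f), sigma = %.4f (SE %.4f)\n",
    x$n, x$n_events, x$mu, x$se_mu, x$sigma, x$se_sigma))
  cat(sprintf("  percentiles (d): p30 = %.2f, p40 = %.2f, p50 = %.2f\n",
              x$percentiles["p30"], x$percentiles["p40"], x$percentiles["p50"]))
  invisible(x)
}

#' Time percentile of a fitted Weibull survivorship model
#'
#' `exp(mu + sigma * log(-log(1 - p)))`: the time by which a fraction `p`
#' of bees has died.
#'
#' @param fit An `hb_weibull_fit`.
#' @param p Cumulative mortality fraction(s) in (0, 1).
#' @return Time(s) in days.
#' @export
weibull_percentile <- function(fit, p) {
  stopifnot(inherits(fit, "hb_weibull_fit"), all(p > 0 & p < 1))
  exp(fit$mu + fit$sigma * log(-log(1 - p)))
}

#' Shape statistic of a survivorship fit
#'
#' The survivorship-curve shape response variable: the 30th percentile
#' minus the 40th percentile. Taken literally on mortality (CDF)
#' percentiles this difference is negative (p30 <= p40 in time units);
#' the field convention is ambiguous between mortality and survivorship
#' percentiles, so both are available -- `convention = "survivor"` uses
#' times at which 30% and 40% of bees remain alive (p70 - p60, positive).
#' Both percentiles are returned alongside the statistic so either
#' convention can be audited.
#'
#' @param fit An `hb_weibull_fit`.
#' @param convention `"cdf"` (default, as written: p30 - p40) or
#'   `"survivor"`.
#' @return List: `value` (days), `p_lo`, `p_hi` (the two percentile times),
#'   `convention`.
#' @export
shape_stat <- function(fit, convention = c("cdf", "survivor")) {
  convention <- match.arg(convention)
  pr <- if (convention == "cdf") c(0.30, 0.40) else c(0.70, 0.60)
  tt <- weibull_percentile(fit, pr)
  list(value = tt[1] - tt[2], p_lo = tt[1], p_hi = tt[2],
       convention = convention)
}

#' Bee-days in a cage over an interval
#'
#' A bee-day is one bee alive for one day. Days are indexed 1, 2, ...; a
#' bee recorded dead at the day-`d` check is counted as alive through day
#' `d` under the default convention (`death_day_weight = 1`: bees are
#' checked once daily, so a bee found dead on day `d` lived most of it),
#' with `0.5` and `0` available to audit the alternative conventions.
#' Censored bees are treated the same way on their removal day.
#'
#' @param trial An [cage_trial()] object.
#' @param interval Integer vector `c(first_day, last_day)`, inclusive.
#' @param death_day_weight Contribution of a bee's recorded death/removal
#'   day: 1 (default), 0.5, or 0.
#' @return Numeric bee-day count.
#' @export
bee_days <- function(trial, interval, death_day_weight = 1) {
  stopifnot(inherits(trial, "hb_cage_trial"), length(interval) == 2,
            interval[1] <= interval[2],
            death_day_weight %in% c(0, 0.5, 1))
  days <- seq(interval[1], interval[2])
  removed_on <- function(d)  # deaths + censorings recorded on day d
    sum(trial$deaths$n[trial$deaths$day == d]) +
    sum(trial$censored$n[trial$censored$day == d])
  removed_before <- function(d)
    sum(trial$deaths$n[trial$deaths$day < d]) +
    sum(trial$censored$n[trial$censored$day < d])
  sum(vapply(days, function(d) {
    trial$n0 - removed_before(d) - (1 - death_day_weight) * removed_on(d)
  }, numeric(1)))
}

#' Syrup consumption per bee per day
#'
#' Observed consumption for a cage divided by the bee-days in the weighing
#' interval, in mg per bee per day.
#'
#' @param trial An [cage_trial()] object with syrup weighings.
#' @param interval `c(first_day, last_day)`; must match a recorded weighing
#'   interval.
#' @param death_day_weight Passed to [bee_days()].
#' @return Consumption in mg/bee/day; `NA` with a warning if the interval
#'   has zero bee-days.
#' @export
consumption_per_bee <- function(trial, interval, death_day_weight = 1) {
  stopifnot(inherits(trial, "hb_cage_trial"))
  if (is.null(trial$syrup)) stopf("cage %s has no syrup weighings", trial$cage_id)
  hit <- trial$syrup$start_day == interval[1] & trial$syrup$end_day == interval[2]
  if (!any(hit))
    stopf("cage %s: no syrup weighing covers days %d-%d",
          trial$cage_id, interval[1], interval[2])
  grams <- trial$syrup$grams[which(hit)[1]]
  bd <- bee_days(trial, interval, death_day_weight)
  if (bd == 0) {
    warnf("cage %s: zero bee-days in days %d-%d", trial$cage_id,
          interval[1], interval[2])
    return(NA_real_)
  }
  grams * 1000 / bd
}
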