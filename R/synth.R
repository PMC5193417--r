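# Synthetic-data generators with known ground truth.
#
# Every input family of the pipeline can be simulated: continuous hive
# weight (diurnal forager mass deficit, trend segments, feeding spikes with
# evaporation, robbing collapses, +/- 20 g uniform sensor noise), internal
# hive temperature (setpoint with regime-dependent daily amplitude and
# ambient coupling), and cage trials (per-bee Weibull mortality binned to
# daily counts, scheduled censoring, consumption at a known per-bee-day
# rate). One scenario seed reproduces a dataset bit-for-bit; per-stream
# substreams are derived deterministically so paired scenarios (e.g. with
# and without a robbing injection) share their noise.
#
# The diurnal forager signature is modelled as a daylight half-sine mass
# deficit (foragers leave in the morning and return by dusk) of depth
# 2 * diurnal_amplitude_kg, whose 24-h Fourier fundamental has amplitude
# exactly diurnal_amplitude_kg; harmonics of the half-sine are orthogonal
# to the 24-h sine fit over full 3-day windows, so the expected fitted
# amplitude is the fundamental times the analytic detrend transfer gain
# (recorded in the ground truth).

#' Specify a synthetic hive-weight scenario
#'
#' @param seed Integer seed; identical seeds reproduce identical data.
#' @param days Number of days simulated (15-min sampling from midnight of
#'   `start_date`).
#' @param base_mass_kg Baseline hive mass.
#' @param diurnal_amplitude_kg Amplitude of the 24-h fundamental of the
#'   daylight forager mass deficit (the half-sine deficit depth is twice
#'   this).
#' @param trend Data.frame `slope_kg_d, span_d`: consecutive linear trend
#'   segments tiling the simulated span (remaining days get slope 0).
#' @param feeding Data.frame `day, hour, mass_kg, evap_frac,
#'   evap_halflife_d`: syrup feeds as instantaneous steps that decay by
#'   evaporation of the water fraction.
#' @param robbing Data.frame `day, start_hour, duration_h, loss_kg`: linear
#'   mass collapses to inject.
#' @param noise_halfwidth_kg Half-width of the uniform sensor noise
#'   (default 0.020 kg, the nominal precision of hive-scale loggers).
#' @param step_min Sampling step, minutes (default 15).
#' @param start_date First simulated date.
#' @param daylight Numeric `c(start_hour, end_hour)` of the forager deficit
#'   (default 06:00-18:00).
#' @return A list of class `hb_hive_scenario`.
#' @export
hive_scenario <- function(seed = 1, days = 10, base_mass_kg = 40,
                          diurnal_amplitude_kg = 0.5, trend = NULL,
                          feeding = NULL, robbing = NULL,
                          noise_halfwidth_kg = 0.020, step_min = 15,
                          start_date = as.Date("2014-07-01"),
                          daylight = c(6, 18)) {
  stopifnot(days >= 1, base_mass_kg > 0, diurnal_amplitude_kg >= 0,
            noise_halfwidth_kg >= 0, step_min > 0,
            length(daylight) == 2, daylight[1] < daylight[2])
  if (!is.null(robbing))
    stopifnot(all(robbing$loss_kg >= 0), all(robbing$duration_h > 0))
  if (!is.null(feeding)) stopifnot(all(feeding$mass_kg >= 0))
  structure(list(seed = seed, days = days, base_mass_kg = base_mass_kg,
                 diurnal_amplitude_kg = diurnal_amplitude_kg, trend = trend,
                 feeding = feeding, robbing = robbing,
                 noise_halfwidth_kg = noise_halfwidth_kg,
                 step_min = step_min, start_date = as.Date(start_date),
                 daylight = daylight),
            class = "hb_hive_scenario")
}

#' Generate a synthetic hive-weight series with ground truth
#'
#' Mass is base + trend + diurnal deficit + feeding steps (decaying by
#' evaporation) + injected robbing ramps + uniform sensor noise. The noise
#' substream depends only on the scenario seed, so two scenarios differing
#' only in injected events share their noise sample-for-sample (paired
#' clean/injected traces).
#'
#' @param scenario A [hive_scenario()].
#' @param hive_id Identifier for the generated series.
#' @return List: `series` (an [`hb_series`][weight_series]) and `truth`, a
#'   list recording every injected component plus
#'   `expected_detrended_amplitude`, the analytic 24-h sine amplitude the
#'   detrend-and-fit pipeline should recover (fundamental x transfer gain
#'   for the default 25-h window).
#' @export
gen_weight_series <- function(scenario, hive_id = "synthetic") {
  stopifnot(inherits(scenario, "hb_hive_scenario"))
  sc <- scenario
  n <- as.integer(sc$days * 24 * 60 / sc$step_min)
  h <- (seq_len(n) - 1L) * sc$step_min / 60  # hours since start midnight
  hod <- h %% 24

  # diurnal daylight half-sine deficit, depth 2A -> 24-h fundamental A
  dl <- sc$daylight
  L <- dl[2] - dl[1]
  diurnal <- ifelse(hod >= dl[1] & hod < dl[2],
                    -2 * sc$diurnal_amplitude_kg * sin(pi * (hod - dl[1]) / L), 0)

  trend <- numeric(n)
  if (!is.null(sc$trend) && nrow(sc$trend)) {
    edges <- cumsum(c(0, sc$trend$span_d))
    dpos <- h / 24
    for (i in seq_len(nrow(sc$trend))) {
      ov <- pmax(0, pmin(dpos, edges[i + 1]) - edges[i])
      trend <- trend + sc$trend$slope_kg_d[i] * ov
    }
  }

  feed <- numeric(n)
  if (!is.null(sc$feeding) && nrow(sc$feeding)) {
    for (i in seq_len(nrow(sc$feeding))) {
      f <- sc$feeding[i, ]
      tf <- (f$day - 1) * 24 + f$hour
      dt <- pmax(0, h - tf)
      on <- h >= tf
      feed <- feed + on * f$mass_kg *
        (1 - f$evap_frac * (1 - 2^(-dt / (24 * f$evap_halflife_d))))
    }
  }

  rob <- numeric(n)
  if (!is.null(sc$robbing) && nrow(sc$robbing)) {
    for (i in seq_len(nrow(sc$robbing))) {
      r <- sc$robbing[i, ]
      ts <- (r$day - 1) * 24 + r$start_hour
      frac <- pmin(1, pmax(0, (h - ts) / r$duration_h))
      rob <- rob - r$loss_kg * frac
    }
  }

  noise <- if (sc$noise_halfwidth_kg > 0)
    with_seed(substream(sc$seed, 1L),
              runif(n, -sc$noise_halfwidth_kg, sc$noise_halfwidth_kg))
  else numeric(n)

  t0 <- as.POSIXct(paste(sc$start_date, "00:00:00"), tz = "UTC")
  series <- weight_series(hive_id, t0 + h * 3600,
                          sc$base_mass_kg + trend + diurnal + feed + rob + noise,
                          nominal_step = sc$step_min)
  gain <- {
    N <- 2L * as.integer(round(25 * 60 / sc$step_min / 2)) + 1L
    th <- pi * (sc$step_min / 60) / 24
    1 - sin(N * th) / (N * sin(th))
  }
  truth <- list(
    diurnal_fundamental_kg = sc$diurnal_amplitude_kg,
    expected_detrended_amplitude = sc$diurnal_amplitude_kg * gain,
    detrend_gain_25h = gain,
    trend = sc$trend, feeding = sc$feeding, robbing = sc$robbing,
    noise_halfwidth_kg = sc$noise_halfwidth_kg)
  list(series = series, truth = truth)
}

#' Specify a synthetic internal-temperature scenario
#'
#' Brood-rearing colonies hold the brood nest near a setpoint with small
#' daily variation; broodless colonies track ambient more, with large daily
#' amplitude. Regimes give the daily amplitude per day range.
#'
#' @param seed Integer seed.
#' @param days Days simulated (30-min sampling).
#' @param setpoint_C Thermoregulation setpoint (default 34.5).
#' @param regimes Data.frame `start_day, end_day, amplitude_C`: daily
#'   sinusoid amplitude per regime (days inclusive, 1-based).
#' @param ambient_coupling Coefficient on the ambient daily sinusoid.
#' @param ambient_amplitude_C Ambient daily amplitude (default 10).
#' @param noise_halfwidth_C Uniform sensor noise half-width (default 0.06,
#'   nominal sensor precision).
#' @param step_min Sampling step, minutes (default 30).
#' @param start_date First simulated date.
#' @return A list of class `hb_temp_scenario`.
#' @export
temp_scenario <- function(seed = 1, days = 10, setpoint_C = 34.5,
                          regimes = data.frame(start_day = 1, end_day = 10,
                                               amplitude_C = 0.2),
                          ambient_coupling = 0, ambient_amplitude_C = 10,
                          noise_halfwidth_C = 0.06, step_min = 30,
                          start_date = as.Date("2014-12-01")) {
  stopifnot(all(regimes$amplitude_C >= 0), ambient_coupling >= 0,
            noise_halfwidth_C >= 0)
  structure(list(seed = seed, days = days, setpoint_C = setpoint_C,
                 regimes = regimes, ambient_coupling = ambient_coupling,
                 ambient_amplitude_C = ambient_amplitude_C,
                 noise_halfwidth_C = noise_halfwidth_C, step_min = step_min,
                 start_date = as.Date(start_date)),
            class = "hb_temp_scenario")
}

#' Generate a synthetic internal-temperature series with ground truth
#'
#' Temperature is setpoint + regime-amplitude daily sinusoid +
#' coupling x ambient daily sinusoid (same phase, peaking mid-afternoon) +
#' uniform noise. Ground truth records the per-day combined sinusoid
#' amplitude and its expected detrended value.
#'
#' @param scenario A [temp_scenario()].
#' @param hive_id Identifier for the generated series.
#' @return List: `series` (temperature `hb_series`) and `truth` (regime
#'   table with `combined_amplitude_C` and `expected_detrended_amplitude`).
#' @export
gen_temp_series <- function(scenario, hive_id = "synthetic") {
  stopifnot(inherits(scenario, "hb_temp_scenario"))
  sc <- scenario
  n <- as.integer(sc$days * 24 * 60 / sc$step_min)
  h <- (seq_len(n) - 1L) * sc$step_min / 60
  day <- floor(h / 24) + 1
  amp <- numeric(n)
  for (i in seq_len(nrow(sc$regimes))) {
    r <- sc$regimes[i, ]
    amp[day >= r$start_day & day <= r$end_day] <- r$amplitude_C
  }
  comb <- amp + sc$ambient_coupling * sc$ambient_amplitude_C
  # daily sinusoid peaking at 15:00
  wave <- comb * cos(2 * pi * (h %% 24 - 15) / 24)
  noise <- if (sc$noise_halfwidth_C > 0)
    with_seed(substream(sc$seed, 2L),
              runif(n, -sc$noise_halfwidth_C, sc$noise_halfwidth_C))
  else numeric(n)
  t0 <- as.POSIXct(paste(sc$start_date, "00:00:00"), tz = "UTC")
  series <- temp_series(hive_id, t0 + h * 3600, sc$setpoint_C + wave + noise,
                        nominal_step = sc$step_min)
  gain <- {
    N <- 2L * as.integer(round(25 * 60 / sc$step_min / 2)) + 1L
    th <- pi * (sc$step_min / 60) / 24
    1 - sin(N * th) / (N * sin(th))
  }
  tr <- sc$regimes
  tr$combined_amplitude_C <- tr$amplitude_C +
    sc$ambient_coupling * sc$ambient_amplitude_C
  tr$expected_detrended_amplitude <- tr$combined_amplitude_C * gain
  list(series = series, truth = list(regimes = tr, detrend_gain_25h = gain))
}

#' Specify a synthetic cage-trial scenario
#'
#' @param seed Integer seed.
#' @param treatments Data.frame `ppb, mu, sigma, consumption_mg_bee_day`:
#'   Weibull AFT survival parameters (log-days) and true consumption rate
#'   per treatment.
#' @param n_cages Replicate cages per treatment (default 10).
#' @param n0 Bees per cage (default 100).
#' @param censor_schedule Data.frame `day, n_removed`: live bees removed for
#'   sampling (default 5 at day 28 and 5 at day 42, the standard protocol).
#' @param final_day Termination day; all survivors censored (default 50).
#' @param weighing_interval_d Length of syrup-weighing intervals (default 7).
#' @param consumption_noise_sd SD of Gaussian noise on weighed grams
#'   (default 0, exact).
#' @return A list of class `hb_cage_scenario`.
#' @export
cage_scenario <- function(seed = 1,
                          treatments = data.frame(
                            ppb = c(0, 5, 20, 100), mu = log(40), sigma = 0.3,
                            consumption_mg_bee_day = 20),
                          n_cages = 10, n0 = 100,
                          censor_schedule = data.frame(day = c(28, 42),
                                                       n_removed = c(5, 5)),
                          final_day = 50, weighing_interval_d = 7,
                          consumption_noise_sd = 0) {
  stopifnot(all(censor_schedule$day < final_day), n0 >= 1, n_cages >= 1)
  structure(list(seed = seed, treatments = treatments, n_cages = n_cages,
                 n0 = n0, censor_schedule = censor_schedule,
                 final_day = final_day,
                 weighing_interval_d = weighing_interval_d,
                 consumption_noise_sd = consumption_noise_sd),
            class = "hb_cage_scenario")
}

#' Generate synthetic cage trials with ground truth
#'
#' Per-bee Weibull death times (`log T = mu + sigma * W`) are binned to
#' daily counts (a bee dying in `(d-1, d]` is recorded dead at the day-`d`
#' check); scheduled censoring removes live bees at the sampling days and
#' all survivors at termination. Weekly syrup consumption is the true rate
#' times the interval's bee-days (default convention), plus optional noise.
#'
#' @param scenario A [cage_scenario()].
#' @return List: `trials` (list of [cage_trial()] objects) and `truth`
#'   (data.frame `cage_id, treatment_ppb, mu, sigma,
#'   consumption_mg_bee_day`).
#' @export
gen_cage_trial <- function(scenario) {
  stopifnot(inherits(scenario, "hb_cage_scenario"))
  sc <- scenario
  trials <- list()
  truth <- list()
  k <- 0L
  for (i in seq_len(nrow(sc$treatments))) {
    tr <- sc$treatments[i, ]
    for (j in seq_len(sc$n_cages)) {
      k <- k + 1L
      cage_id <- sprintf("c%02d_ppb%g", k, tr$ppb)
      T <- with_seed(substream(sc$seed, 100L + k), {
        u <- runif(sc$n0)
        tt <- exp(tr$mu + tr$sigma * log(-log(u)))
        list(times = tt, pick = runif(sc$n0))  # pick orders censor sampling
      })
      death_day <- ceiling(T$times)
      censored_at <- rep(NA_real_, sc$n0)
      for (r in seq_len(nrow(sc$censor_schedule))) {
        cd <- sc$censor_schedule$day[r]
        alive <- which(death_day > cd & is.na(censored_at))
        take <- alive[order(T$pick[alive])][seq_len(min(sc$censor_schedule$n_removed[r],
                                                        length(alive)))]
        censored_at[take] <- cd
      }
      surv <- which(death_day > sc$final_day & is.na(censored_at))
      censored_at[surv] <- sc$final_day
      obs_death <- is.na(censored_at) & death_day <= sc$final_day
      deaths <- as.data.frame(table(day = death_day[obs_death]),
                              stringsAsFactors = FALSE)
      deaths <- data.frame(day = as.integer(deaths$day), n = deaths$Freq)
      cens <- as.data.frame(table(day = censored_at[!is.na(censored_at)]),
                            stringsAsFactors = FALSE)
      cens <- data.frame(day = as.integer(as.numeric(cens$day)), n = cens$Freq)
      trial <- cage_trial(cage_id, tr$ppb, n0 = sc$n0, deaths = deaths,
                          censored = cens)
      starts <- seq(1, sc$final_day, by = sc$weighing_interval_d)
      syr <- data.frame(start_day = starts,
                        end_day = pmin(starts + sc$weighing_interval_d - 1,
                                       sc$final_day))
      syr$grams <- vapply(seq_len(nrow(syr)), function(r)
        tr$consumption_mg_bee_day *
          bee_days(trial, c(syr$start_day[r], syr$end_day[r])) / 1000,
        numeric(1))
      if (sc$consumption_noise_sd > 0)
        syr$grams <- syr$grams + with_seed(substream(sc$seed, 500L + k),
                                           rnorm(nrow(syr), 0, sc$consumption_noise_sd))
      trial$syrup <- syr
      trials[[cage_id]] <- trial
      truth[[cage_id]] <- data.frame(
        cage_id = cage_id, treatment_ppb = tr$ppb, mu = tr$mu, sigma = tr$sigma,
        consumption_mg_bee_day = tr$consumption_mg_bee_day,
        stringsAsFactors = FALSE)
    }
  }
  list(trials = trials, truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}
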