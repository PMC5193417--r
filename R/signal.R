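# Trend/residual decomposition of continuous hive series and daily
# sine-amplitude statistics.
#
# The decomposition follows the standard continuous-monitoring protocol:
# the trend is a 25-h centred running average (25 h rather than 24 h so the
# window never aligns exactly with the diurnal cycle), the within-day signal
# is the residual raw - trend, and daily variability is summarised by the
# amplitude of a fixed-period 24-h sine fitted to 3-day windows of residuals
# stepped by one day.

#' Centred running average of a series
#'
#' The smoothed value at sample `i` is the mean of all samples whose
#' timestamps lie within `window_h / 2` hours of `time[i]`, both window
#' boundaries included (the symmetric closed window keeps the trend at zero
#' phase lag, and makes the mean of a linear ramp exact). The output is
#' masked (`NA`) wherever the window overlaps the series boundary or an
#' annotated gap: gaps invalidate windows, they are never filled.
#'
#' @param series An [`hb_series`][weight_series].
#' @param window_h Window length in hours (default 25).
#' @return Numeric vector, same length as the series, `NA` outside the
#'   valid region; attribute `valid` carries the logical mask.
#' @export
running_average <- function(series, window_h = 25) {
  stopifnot(inherits(series, "hb_series"), window_h > 0)
  t <- as.numeric(series$time)
  v <- series$value
  n <- length(v)
  half <- window_h * 3600 / 2
  eps <- 1e-6  # sub-microsecond slop so exact boundary samples are included
  lo <- findInterval(t - half - eps, t) + 1L
  hi <- findInterval(t + half + eps, t)
  cs <- c(0, cumsum(v))
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  valid <- (t - half >= t[1] - eps) & (t + half <= t[n] + eps)
  if (any(series$gap_after)) {
    gi <- which(series$gap_after)
    for (g in gi) {  # window [t-half, t+half] intersecting open gap (t_g, t_{g+1})
      hit <- (t + half > t[g] + eps) & (t - half < t[g + 1L] - eps)
      valid <- valid & !hit
    }
  }
  out[!valid] <- NA_real_
  if (!any(valid)) warnf("series shorter than one window: empty valid region")
  attr(out, "valid") <- valid
  out
}

#' Detrend a series against its running average
#'
#' Residuals are `raw - running_average` (so a midday forager mass deficit
#' is negative); the amplitude statistics downstream are invariant to this
#' sign convention. Residuals are defined only where the centred window is
#' gap-free and fully inside the series.
#'
#' @inheritParams running_average
#' @return An object of class `hb_detrended`: list with the parent `series`,
#'   `residual` (NA outside the valid region), `trend`, `window_h`, `valid`.
#' @export
detrend <- function(series, window_h = 25) {
  tr <- running_average(series, window_h)
  structure(
    list(series = series, trend = as.numeric(tr),
         residual = series$value - as.numeric(tr),
         window_h = window_h, valid = attr(tr, "valid")),
    class = "hb_detrended")
}

#' @export
print.hb_detrended <- function(x, ...) {
  cat(sprintf("<detrended %s series> hive %s: %d/%d valid samples, window %g h\n",
              x$series$kind, x$series$hive_id, sum(x$valid), length(x$valid),
              x$window_h))
  invisible(x)
}

#' Transfer gain of the detrender at a given period
#'
#' A sinusoid of period `period_h` survives the running-average detrend with
#' its amplitude multiplied by `1 - D`, where `D` is the discrete Dirichlet
#' mean of the sinusoid over the window (closed form for a regular grid).
#' For the defaults (24-h period, 25-h window, 15-min sampling) the gain is
#' about 1.049: the 25-h trend slightly anti-correlates with the 24-h cycle,
#' so residual amplitudes sit just above the raw ones.
#'
#' @param window_h Running-average window, hours.
#' @param period_h Sinusoid period, hours.
#' @param step_min Sampling step, minutes.
#' @return Scalar gain applied to the amplitude of the sinusoid.
#' @export
detrend_gain <- function(window_h = 25, period_h = 24, step_min = 15) {
  N <- 2L * as.integer(round(window_h * 60 / step_min / 2)) + 1L
  theta <- pi * (step_min / 60) / period_h
  1 - sin(N * theta) / (N * sin(theta))
}

#' Fit a fixed-period sine to one window of detrended data
#'
#' Least-squares fit of `y(t) = a sin(wt) + b cos(wt) + c` with
#' `w = 2 pi / period_h` and `t` in hours since the window start (00:00 of
#' `window_start_day`). Amplitude is `sqrt(a^2 + b^2)` (>= 0), phase is
#' `atan2(b, a)` in `[0, 2 pi)`. The fit requires at least
#' `min_frac` of the window's nominal samples to be present and valid;
#' otherwise a no-fit result carrying the reason is returned (see
#' [is_nofit()]).
#'
#' @param detrended An `hb_detrended` object.
#' @param window_start_day Date of the window's first day.
#' @param span_d Window span in days (default 3).
#' @param period_h Fixed sine period in hours (default 24; the period is a
#'   configuration knob, never fitted).
#' @param min_frac Minimum fraction of nominal samples required (default 0.5).
#' @return A list of class `hb_sinefit`: `amplitude`, `phase`, `offset`,
#'   `rmse`, `n`, `start_day`, `center_day`, `span_d`, `period_h` -- or an
#'   `hb_nofit` with a `reason`.
#' @export
fit_sine_window <- function(detrended, window_start_day, span_d = 3,
                            period_h = 24, min_frac = 0.5) {
  stopifnot(inherits(detrended, "hb_detrended"))
  day0 <- as.Date(window_start_day)
  t0 <- as.POSIXct(paste(day0, "00:00:00"), tz = "UTC")
  t <- as.numeric(detrended$series$time) - as.numeric(t0)
  inwin <- t >= 0 & t < span_d * 86400
  ok <- inwin & detrended$valid
  nominal <- span_d * 24 * 60 / detrended$series$nominal_step
  if (sum(ok) < min_frac * nominal)
    return(structure(list(reason = sprintf(
      "window %s: %d of %g nominal samples valid (< %g%%)",
      day0, sum(ok), nominal, 100 * min_frac),
      start_day = day0), class = "hb_nofit"))
  th <- t[ok] / 3600
  y <- detrended$residual[ok]
  w <- 2 * pi / period_h
  X <- cbind(s = sin(w * th), c = cos(w * th), 1)
  fit <- stats::lm.fit(X, y)
  a <- fit$coefficients[["s"]]; b <- fit$coefficients[["c"]]
  structure(list(
    amplitude = sqrt(a^2 + b^2),
    phase = atan2(b, a) %% (2 * pi),
    offset = unname(fit$coefficients[[3]]),
    rmse = sqrt(mean(fit$residuals^2)),
    n = sum(ok), start_day = day0,
    center_day = day0 + floor(span_d / 2),
    span_d = span_d, period_h = period_h), class = "hb_sinefit")
}

#' Is this a no-fit result?
#' @param x Object returned by a fitting routine.
#' @return TRUE if `x` is a no-fit marker carrying a `reason`.
#' @export
is_nofit <- function(x) inherits(x, "hb_nofit")

#' Daily sine-amplitude series from detrended data
#'
#' One `span_d`-day window per start day, stepping by one day; each fit is
#' assigned to the window's centre day. Days whose windows fail the sample
#' validity threshold are absent from the output.
#'
#' @inheritParams fit_sine_window
#' @return A data.frame of class `hb_amplitudes`: `hive_id, day, kind,
#'   amplitude, phase, offset, rmse, n`, at most one row per day; attributes
#'   `span_d`, `period_h`, `thin_step` (NA until thinned).
#' @export
amplitude_series <- function(detrended, span_d = 3, period_h = 24,
                             min_frac = 0.5) {
  stopifnot(inherits(detrended, "hb_detrended"))
  tm <- detrended$series$time
  d0 <- as.Date(tm[1], tz = "UTC")
  d1 <- as.Date(tm[length(tm)], tz = "UTC")
  starts <- seq(d0, d1 - span_d + 1, by = "day")
  if (length(starts) < 1L) stopf("series spans fewer than %d days", span_d)
  rows <- list()
  for (s in seq_along(starts)) {
    f <- fit_sine_window(detrended, starts[s], span_d, period_h, min_frac)
    if (is_nofit(f)) next
    rows[[length(rows) + 1L]] <- data.frame(
      hive_id = detrended$series$hive_id, day = f$center_day,
      kind = detrended$series$kind, amplitude = f$amplitude, phase = f$phase,
      offset = f$offset, rmse = f$rmse, n = f$n, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hive_id = character(), day = as.Date(character()),
               kind = character(), amplitude = numeric(), phase = numeric(),
               offset = numeric(), rmse = numeric(), n = integer(),
               stringsAsFactors = FALSE)
  structure(out, class = c("hb_amplitudes", "data.frame"),
            span_d = span_d, period_h = period_h, thin_step = NA_real_)
}

#' Thin an amplitude series for repeated-measures analysis
#'
#' Keeps records at centre days `anchor, anchor + step_d, ...` so that
#' consecutive kept 3-day windows share no samples (the fitting windows of
#' records 5 days apart are separated by 2 clear days). By default the
#' anchor is the first available centre day. A step that violates the
#' no-overlap guarantee (`step_d < span_d + 1`) is refused unless
#' `allow_overlap = TRUE`.
#'
#' @param amps An `hb_amplitudes` data.frame.
#' @param step_d Days between kept records (default 5).
#' @param anchor Date of the first kept record; default first centre day.
#' @param allow_overlap Permit steps that leave overlapping windows.
#' @return The thinned `hb_amplitudes`, attribute `thin_step` set.
#' @export
thin_for_rm <- function(amps, step_d = 5, anchor = NULL, allow_overlap = FALSE) {
  stopifnot(inherits(amps, "hb_amplitudes"))
  span_d <- attr(amps, "span_d") %||% 3
  if (step_d < span_d + 1 && !allow_overlap)
    stopf("step_d = %g leaves %g-day windows overlapping; need step_d >= %g",
          step_d, span_d, span_d + 1)
  if (nrow(amps) == 0L) {
    attr(amps, "thin_step") <- step_d
    return(amps)
  }
  anchor <- as.Date(anchor %||% min(amps$day))
  keep <- as.numeric(amps$day - anchor) %% step_d == 0 & amps$day >= anchor
  out <- amps[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "span_d") <- span_d
  attr(out, "period_h") <- attr(amps, "period_h")
  attr(out, "thin_step") <- step_d
  out
}

#' Hive weight at the midnight starting a given date
#'
#' Returns the sample nearest to 00:00 of `date` within `tol_min` minutes;
#' ties are broken toward the earlier sample. `NA` if no sample is close
#' enough (e.g. a logger gap around midnight).
#'
#' @param series An `hb_series`.
#' @param date Date (the midnight at the start of this date is targeted).
#' @param tol_min Tolerance in minutes (default 30).
#' @return Numeric value (kg for weight series), or `NA_real_`.
#' @export
midnight_weight <- function(series, date, tol_min = 30) {
  stopifnot(inherits(series, "hb_series"))
  target <- as.numeric(as.POSIXct(paste(as.Date(date), "00:00:00"), tz = "UTC"))
  t <- as.numeric(series$time)
  dist <- abs(t - target)
  i <- which(dist <= tol_min * 60 + 1e-6)
  if (!length(i)) return(NA_real_)
  # nearest; ties toward the earlier sample (which.min returns the first)
  series$value[i[which.min(round(dist[i], 6))]]
}

#' Adult bee mass from midnight hive weight
#'
#' The adult population mass is the midnight hive weight minus the tare of
#' the hive hardware (lid, inner cover, box, bottom board, entrance reducer,
#' feeder, and the frames as weighed at establishment) and, when supplied,
#' the current frame weights from the inspection (so comb and stores drawn
#' since establishment are not attributed to bees). Negative estimates are
#' floored at zero and flagged rather than erroring: comb growth can exceed
#' the tare assumptions.
#'
#' @param midnight_kg Total hive weight at the midnight before inspection.
#' @param tare_components_kg Summed hardware tare, kg.
#' @param frames_current_kg Current total frame weight, kg; `NULL` to use
#'   the start-tare-only mode (frames included in the tare).
#' @return List of class `hb_adult_mass`: `kg`, `negative_flag`, `mode`
#'   (`"current-frames"` or `"start-tare-only"`).
#' @export
adult_mass <- function(midnight_kg, tare_components_kg, frames_current_kg = NULL) {
  stopifnot(midnight_kg >= 0, tare_components_kg >= 0)
  mode <- if (is.null(frames_current_kg)) "start-tare-only" else "current-frames"
  raw <- midnight_kg - tare_components_kg - (frames_current_kg %||% 0)
  structure(list(kg = max(raw, 0), negative_flag = raw < 0, mode = mode),
            class = "hb_adult_mass")
}
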