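# Behavioural episode classification from hive-weight dynamics.
#
# Two detectors operate on different time scales. Nectar flows are multi-day
# runs of largely monotonic weight gain (strictly more than 7 days at the
# default settings). Robbing -- foreign foragers stripping stored honey --
# shows up either as an excessive daily net loss (> 1.5 kg/day) or as a
# rapid collapse (>= 2 kg peak-to-trough within less than 6 h).

#' Per-day net weight change from midnight weights
#'
#' `delta(day) = midnight(day + 1) - midnight(day)`: the net change over the
#' calendar day. Days with a missing midnight on either side yield `NA`.
#'
#' @param series An [`hb_series`][weight_series] spanning at least 2 midnights.
#' @param tol_min Midnight matching tolerance, minutes (default 30).
#' @return Data.frame `day` (Date), `delta` (kg).
#' @export
daily_deltas <- function(series, tol_min = 30) {
  stopifnot(inherits(series, "hb_series"))
  d0 <- as.Date(series$time[1], tz = "UTC")
  d1 <- as.Date(series$time[length(series$time)], tz = "UTC")
  days <- seq(d0, d1 + 1, by = "day")
  mw <- vapply(days, function(d) midnight_weight(series, d, tol_min), numeric(1))
  if (sum(!is.na(mw)) < 2L) stopf("series spans fewer than 2 midnights")
  data.frame(day = days[-length(days)], delta = diff(mw))
}

#' Detect nectar flows from daily weight deltas
#'
#' A nectar flow is a maximal run of consecutive days that starts and ends
#' on a rising day, keeps the fraction of rising days at or above
#' `min_fraction_rising` ("largely monotonic"), has positive cumulative
#' gain, and lasts strictly more than `min_duration_d` days. Runs are broken
#' by missing deltas.
#'
#' @param deltas Data.frame from [daily_deltas()] (`day`, `delta`).
#' @param min_duration_d Minimum duration in days, strict (default 7: a
#'   7-day run does not qualify, an 8-day run does).
#' @param min_fraction_rising Minimum fraction of rising days (default 0.8).
#' @return Data.frame of class `hb_nectar_flows`: `start_day, end_day,
#'   duration_d, cumulative_gain_kg, fraction_rising` (zero rows if none).
#' @export
detect_nectar_flows <- function(deltas, min_duration_d = 7,
                                min_fraction_rising = 0.8) {
  stopifnot(all(c("day", "delta") %in% names(deltas)))
  empty <- data.frame(start_day = as.Date(character()),
                      end_day = as.Date(character()), duration_d = integer(),
                      cumulative_gain_kg = numeric(), fraction_rising = numeric())
  class(empty) <- c("hb_nectar_flows", "data.frame")
  n <- nrow(deltas)
  if (n == 0L) return(empty)
  deltas <- deltas[order(deltas$day), , drop = FALSE]
  rising <- !is.na(deltas$delta) & deltas$delta > 0
  avail <- !is.na(deltas$delta)
  # contiguity also requires consecutive calendar days
  daynum <- as.numeric(deltas$day)
  events <- list()
  i <- 1L
  while (i <= n) {
    if (!rising[i]) { i <- i + 1L; next }
    # extend as far as the rising fraction allows; runs break at missing
    # deltas or calendar discontinuities; the kept end must be a rising day
    best_k <- i
    nrise <- 0L
    k <- i
    while (k <= n && avail[k] && (k == i || daynum[k] - daynum[k - 1L] == 1)) {
      nrise <- nrise + as.integer(rising[k])
      frac <- nrise / (k - i + 1L)
      if (frac >= min_fraction_rising && rising[k]) best_k <- k
      k <- k + 1L
    }
    run <- i:best_k
    gain <- sum(deltas$delta[run])
    dur <- length(run)
    if (dur > min_duration_d && gain > 0) {
      events[[length(events) + 1L]] <- data.frame(
        start_day = deltas$day[i], end_day = deltas$day[best_k],
        duration_d = dur, cumulative_gain_kg = gain,
        fraction_rising = mean(rising[run]))
    }
    i <- best_k + 1L
  }
  out <- if (length(events)) do.call(rbind, events) else empty
  class(out) <- c("hb_nectar_flows", "data.frame")
  rownames(out) <- NULL
  out
}

#' Detect robbing events from a sub-daily weight series
#'
#' Two screens are applied and overlapping flags merged into single events:
#' \describe{
#'   \item{daily}{days whose net loss strictly exceeds
#'     `daily_loss_thresh_kg` (a colony evaporating syrup loses weight, but
#'     more than 1.5 kg in a day is excessive).}
#'   \item{rapid}{intervals whose peak-to-trough drop reaches
#'     `rapid_loss_kg` within strictly less than `rapid_window_h` hours
#'     (peak-to-trough, not endpoints: robbing signatures are monotone
#'     collapses, and peak-to-trough is robust to pre/post noise).}
#' }
#' When `feeding` is supplied and `exclude_feeding_days = TRUE`, feeding
#' dates are dropped from the daily screen (evaporative loss after a feed
#' can mimic a daily-rate flag); the flag defaults to off.
#'
#' @param series An `hb_series` (weight).
#' @param daily_loss_thresh_kg Daily net-loss threshold, strict (default 1.5).
#' @param rapid_loss_kg Rapid-drop threshold, kg (default 2).
#' @param rapid_window_h Rapid-drop window, hours, strict (default 6).
#' @param feeding Optional [`hb_schedule`][feeding_schedule] for this hive.
#' @param exclude_feeding_days Drop feeding dates from the daily screen.
#' @param tol_min Midnight matching tolerance for the daily screen.
#' @return Data.frame of class `hb_robbing`: `hive_id, start, end, loss_kg,
#'   loss_window_h, trigger` (`daily_rate`, `rapid_drop`, or both joined by
#'   `+`); events are disjoint in time.
#' @export
detect_robbing <- function(series, daily_loss_thresh_kg = 1.5,
                           rapid_loss_kg = 2, rapid_window_h = 6,
                           feeding = NULL, exclude_feeding_days = FALSE,
                           tol_min = 30) {
  stopifnot(inherits(series, "hb_series"))
  t <- as.numeric(series$time)
  v <- series$value
  n <- length(v)
  flags <- list()  # each: start, end (numeric secs), loss, trigger

  # --- daily screen ----------------------------------------------------
  dd <- tryCatch(daily_deltas(series, tol_min), error = function(e) NULL)
  if (!is.null(dd)) {
    if (!is.null(feeding) && exclude_feeding_days) {
      fd <- as.Date(feeding$date[feeding$hive_id == series$hive_id |
                                   !("hive_id" %in% names(feeding))])
      dd <- dd[!(dd$day %in% fd), , drop = FALSE]
    }
    hit <- which(!is.na(dd$delta) & -dd$delta > daily_loss_thresh_kg)
    for (i in hit) {
      s <- as.numeric(as.POSIXct(paste(dd$day[i], "00:00:00"), tz = "UTC"))
      flags[[length(flags) + 1L]] <- list(start = s, end = s + 86400,
                                          loss = -dd$delta[i],
                                          trigger = "daily_rate")
    }
  }

  # --- rapid screen: running max within the trailing open window -------
  win <- rapid_window_h * 3600
  lo <- findInterval(t - win, t) + 1L  # first j with t[j] > t[i] - win (strict)
  for (i in seq_len(n)) {
    j <- lo[i]
    if (j >= i) next
    seg <- j:i
    pk <- seg[which.max(v[seg])]
    drop <- v[pk] - v[i]
    if (drop >= rapid_loss_kg) {
      flags[[length(flags) + 1L]] <- list(start = t[pk], end = t[i],
                                          loss = drop, trigger = "rapid_drop")
    }
  }

  empty <- data.frame(hive_id = character(), start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"), loss_kg = numeric(),
                      loss_window_h = numeric(), trigger = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("hb_robbing", "data.frame")
  if (!length(flags)) return(empty)

  # --- merge overlapping flags into disjoint events --------------------
  fl <- do.call(rbind, lapply(flags, function(f)
    data.frame(start = f$start, end = f$end, loss = f$loss, trigger = f$trigger,
               stringsAsFactors = FALSE)))
  fl <- fl[order(fl$start, fl$end), , drop = FALSE]
  merged <- list()
  cur <- fl[1, ]
  cur_triggers <- cur$trigger
  for (r in seq_len(nrow(fl))[-1]) {
    if (fl$start[r] <= cur$end) {
      cur$end <- max(cur$end, fl$end[r])
      cur$loss <- max(cur$loss, fl$loss[r])
      cur_triggers <- union(cur_triggers, fl$trigger[r])
    } else {
      cur$trigger <- paste(sort(cur_triggers), collapse = "+")
      merged[[length(merged) + 1L]] <- cur
      cur <- fl[r, ]
      cur_triggers <- cur$trigger
    }
  }
  cur$trigger <- paste(sort(cur_triggers), collapse = "+")
  merged[[length(merged) + 1L]] <- cur
  mg <- do.call(rbind, merged)
  out <- data.frame(
    hive_id = series$hive_id,
    start = as.POSIXct(mg$start, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(mg$end, origin = "1970-01-01", tz = "UTC"),
    loss_kg = mg$loss,
    loss_window_h = (mg$end - mg$start) / 3600,
    trigger = mg$trigger, stringsAsFactors = FALSE)
  class(out) <- c("hb_robbing", "data.frame")
  rownames(out) <- NULL
  out
}
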