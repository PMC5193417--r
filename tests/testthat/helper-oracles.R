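# Independent oracles and fixture builders. These deliberately re-derive
# quantities by brute force or closed form, staying off the package's own
# computational paths.

# Regular 15-min weight series over `days` days starting at midnight.
make_series <- function(values, step_min = 15, start = "2014-07-01",
                        hive_id = "h1") {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  weight_series(hive_id, t0 + (seq_along(values) - 1) * step_min * 60, values,
                nominal_step = step_min)
}

hours_grid <- function(days, step_min = 15) {
  n <- days * 24 * 60 / step_min
  (seq_len(n) - 1) * step_min / 60
}

# Brute-force centred running mean (closed window), NA where the window
# spills over the series boundary. For gap-free series only.
brute_running_average <- function(series, window_h = 25) {
  t <- as.numeric(series$time)
  half <- window_h * 3600 / 2
  sapply(seq_along(t), function(i) {
    if (t[i] - half < t[1] - 1e-6 || t[i] + half > t[length(t)] + 1e-6)
      return(NA_real_)
    mean(series$value[t >= t[i] - half - 1e-6 & t <= t[i] + half + 1e-6])
  })
}

# Wrap a hand-built residual vector as a detrended object (identity trend),
# so sine-fitting can be tested in isolation from the running average.
as_detrended <- function(series, residual, window_h = 25) {
  structure(list(series = series, trend = series$value - residual,
                 residual = residual, window_h = window_h,
                 valid = rep(TRUE, length(residual))),
            class = "hb_detrended")
}

# Per-bee enumeration of bee-days: each bee contributes 1 for every
# interval day strictly before its removal day and `w` on the removal day.
bee_days_enum <- function(trial, interval, w = 1) {
  removal <- c(rep(trial$deaths$day, trial$deaths$n),
               rep(trial$censored$day, trial$censored$n))
  removal <- c(removal, rep(Inf, trial$n0 - length(removal)))
  days <- seq(interval[1], interval[2])
  total <- 0
  for (r in removal) total <- total + sum(days < r) + w * sum(days == r)
  total
}

# Direct maximum likelihood for the right-censored Weibull AFT model
# (extreme-value density on log time), independent of survival::survreg.
weibull_ml_oracle <- function(records) {
  nll <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    z <- (log(records$time) - mu) / s
    -sum(ifelse(records$status == 1,
                -log(s) - log(records$time) + z - exp(z),
                -exp(z)))
  }
  o <- stats::optim(c(mean(log(records$time)), log(0.5)), nll,
                    method = "BFGS", hessian = TRUE)
  list(mu = o$par[1], sigma = exp(o$par[2]),
       se_mu = sqrt(diag(solve(o$hessian)))[1])
}

# Random cage trial for bee-day oracle checks.
random_trial <- function(seed, n0 = 30, span = 20) {
  set.seed(seed)
  nd <- sample(0:10, 1)
  deaths <- if (nd > 0) {
    d <- table(sample(seq_len(span), nd, replace = TRUE))
    data.frame(day = as.integer(names(d)), n = as.integer(d))
  } else data.frame(day = integer(), n = integer())
  nc <- sample(0:5, 1)
  censored <- if (nc > 0) {
    d <- table(sample(seq_len(span), nc, replace = TRUE))
    data.frame(day = as.integer(names(d)), n = as.integer(d))
  } else data.frame(day = integer(), n = integer())
  cage_trial(sprintf("r%d", seed), 0, n0 = n0, deaths = deaths,
             censored = censored)
}
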