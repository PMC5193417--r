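# Trend removal and daily sine-amplitude estimation.

test_that("running average preserves constants and linear ramps exactly", {
  s <- make_series(rep(50, 960))
  ra <- running_average(s)
  expect_true(all(ra[attr(ra, "valid")] == 50))
  # centred mean of a linear function is the function itself
  h <- hours_grid(10)
  ramp <- make_series(30 + 0.1 * h)
  ra <- running_average(ramp)
  v <- attr(ra, "valid")
  expect_equal(ra[v], 30 + 0.1 * h[v], tolerance = 1e-12)
  # valid region excludes half a window at each end
  expect_equal(sum(!v), 2 * 50)  # 12.5 h = 50 samples per side
})

test_that("running average of a 24-h sinusoid matches the Dirichlet closed form", {
  h <- hours_grid(10)
  w <- 2 * pi / 24
  s <- make_series(40 + sin(w * h))
  ra <- running_average(s)
  v <- attr(ra, "valid")
  N <- 101; theta <- pi * 0.25 / 24
  D <- sin(N * theta) / (N * sin(theta))  # discrete mean over the window
  expect_equal(ra[v], 40 + D * sin(w * h[v]), tolerance = 1e-9)
  # and detrending leaves the complementary sinusoid: gain 1 - D
  dt <- detrend(s)
  expect_equal(dt$residual[v], (1 - D) * sin(w * h[v]), tolerance = 1e-9)
  expect_equal(detrend_gain(25, 24, 15), 1 - D, tolerance = 1e-12)
})

test_that("running average equals the brute-force window mean on random series", {
  for (seed in 1:20) {
    set.seed(seed)
    s <- make_series(40 + cumsum(rnorm(480, 0, 0.05)))
    ra <- running_average(s)
    ref <- brute_running_average(s)
    expect_equal(as.numeric(ra), ref, tolerance = 1e-10)
  }
})

test_that("windows overlapping gaps or boundaries are masked, not filled", {
  tm <- as.POSIXct("2014-07-01 00:00:00", tz = "UTC") + (0:959) * 900
  keep <- as.Date(tm, tz = "UTC") != as.Date("2014-07-05")
  s <- weight_series("h1", tm[keep], rep(40, sum(keep)))
  ra <- running_average(s)
  v <- attr(ra, "valid")
  t <- as.numeric(s$time)
  gap_lo <- as.numeric(as.POSIXct("2014-07-04 23:45:00", tz = "UTC"))
  gap_hi <- as.numeric(as.POSIXct("2014-07-06 00:00:00", tz = "UTC"))
  near_gap <- t + 12.5 * 3600 > gap_lo & t - 12.5 * 3600 < gap_hi
  expect_true(all(is.na(ra[near_gap])))
  expect_false(anyNA(ra[v]))
  # shorter than one window: empty valid region with a warning
  expect_warning(ra2 <- running_average(make_series(rep(40, 8))), "empty valid")
  expect_true(all(is.na(ra2)))
})

test_that("detrend residuals are zero for constant input and an impulse has
           a 25-hour support", {
  s <- make_series(rep(42, 960))
  dt <- detrend(s)
  expect_true(all(dt$residual[dt$valid] == 0))

  imp <- s
  imp$value[480] <- imp$value[480] + 1
  di <- detrend(imp)
  changed <- which(abs(di$residual - dt$residual) > 1e-12 &
                     di$valid & dt$valid)
  support_h <- as.numeric(difftime(s$time[max(changed)], s$time[min(changed)],
                                   units = "hours"))
  expect_equal(support_h, 25)
})

test_that("sine fits recover noiseless signals exactly and noisy amplitudes
           within their standard error", {
  h <- hours_grid(3)
  base <- make_series(rep(40, length(h)))
  sig <- 0.8 * sin(2 * pi * h / 24 + 1.0)
  f <- fit_sine_window(as_detrended(base, sig), "2014-07-01")
  expect_equal(f$amplitude, 0.8, tolerance = 1e-9)
  expect_equal(f$phase, 1.0, tolerance = 1e-9)
  expect_equal(f$offset, 0, tolerance = 1e-9)
  expect_equal(f$rmse, 0, tolerance = 1e-9)

  # all-zero residuals: amplitude 0
  f0 <- fit_sine_window(as_detrended(base, rep(0, length(h))), "2014-07-01")
  expect_equal(f0$amplitude, 0)

  # Gaussian noise sigma = 0.05 on 288 points: amplitude within 3 SE,
  # SE(amplitude) ~ sigma * sqrt(2/n) for the orthogonal sine/cosine design
  set.seed(11)
  ok <- vapply(1:20, function(i) {
    fn <- fit_sine_window(as_detrended(base, sig + rnorm(length(h), 0, 0.05)),
                          "2014-07-01")
    abs(fn$amplitude - 0.8) < 3 * 0.05 * sqrt(2 / length(h))
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("amplitude is invariant to residual sign and raw-series offset", {
  h <- hours_grid(3)
  base <- make_series(rep(40, length(h)))
  sig <- 0.6 * sin(2 * pi * h / 24 + 0.4)
  a1 <- fit_sine_window(as_detrended(base, sig), "2014-07-01")$amplitude
  a2 <- fit_sine_window(as_detrended(base, -sig), "2014-07-01")$amplitude
  expect_equal(a1, a2, tolerance = 1e-12)
  s <- make_series(40 + 0.5 * sin(2 * pi * hours_grid(6) / 24))
  s2 <- s; s2$value <- s2$value + 7.3
  expect_equal(amplitude_series(detrend(s))$amplitude,
               amplitude_series(detrend(s2))$amplitude, tolerance = 1e-9)
})

test_that("amplitude series yields one centre-day record per full window", {
  mk <- function(days) make_series(40 + 0.5 * sin(2 * pi * hours_grid(days) / 24))
  a10 <- amplitude_series(detrend(mk(10)))
  expect_equal(nrow(a10), 8L)
  expect_equal(a10$day, as.Date("2014-07-02") + 0:7)
  expect_false(anyDuplicated(a10$day) > 0)
  a3 <- amplitude_series(detrend(mk(3)))
  expect_equal(nrow(a3), 1L)
  # a pure 24-h sinusoid gives constant amplitudes across full windows
  interior <- a10[a10$n == 288, ]
  expect_lt(diff(range(interior$amplitude)), 1e-6)
})

test_that("windows touching a 1-day gap fail the validity threshold", {
  tm <- as.POSIXct("2014-07-01 00:00:00", tz = "UTC") + (0:959) * 900
  h <- as.numeric(tm - tm[1], units = "hours")
  keep <- as.Date(tm, tz = "UTC") != as.Date("2014-07-05")
  s <- weight_series("h1", tm[keep], (40 + 0.5 * sin(2 * pi * h / 24))[keep])
  a <- amplitude_series(detrend(s))
  expect_equal(a$day, as.Date(c("2014-07-02", "2014-07-03", "2014-07-07",
                                "2014-07-08", "2014-07-09")))
})

test_that("thinning keeps non-overlapping windows only", {
  amps <- structure(
    data.frame(hive_id = "h1", day = as.Date("2014-07-02") + 0:29,
               kind = "weight", amplitude = runif(30), phase = 0, offset = 0,
               rmse = 0, n = 288L),
    class = c("hb_amplitudes", "data.frame"),
    span_d = 3, period_h = 24, thin_step = NA_real_)
  th <- thin_for_rm(amps, 5)
  expect_equal(nrow(th), 6L)
  expect_true(all(diff(th$day) == 5))
  # kept 3-day windows centred 5 days apart share no samples (2 clear days)
  expect_gte(min(diff(th$day)) - 3, 2)
  expect_error(thin_for_rm(amps, 3), "overlapping")
  expect_equal(nrow(thin_for_rm(amps, 3, allow_overlap = TRUE)), 10L)
  expect_equal(nrow(thin_for_rm(amps[0, ], 5)), 0L)
})

test_that("midnight weight picks the nearest sample with earlier-tie rule", {
  t0 <- as.POSIXct("2014-07-02 00:00:00", tz = "UTC")
  s <- weight_series("h1", t0 + c(-86400, -450, 450, 86400),
                     c(40, 41.1, 41.3, 42))
  expect_equal(midnight_weight(s, "2014-07-02"), 41.1)  # tie -> earlier
  s2 <- weight_series("h1", t0 + c(-86400, 0, 86400), c(40, 41.2, 42))
  expect_equal(midnight_weight(s2, "2014-07-02"), 41.2)
  s3 <- weight_series("h1", t0 + c(-7200, 3600), c(40, 41))  # 2-h hole
  expect_true(is.na(midnight_weight(s3, "2014-07-02")))
})

test_that("adult mass subtracts tare, floors at zero and records its mode", {
  am <- adult_mass(45, 20, 22.5)
  expect_equal(am$kg, 2.5)
  expect_false(am$negative_flag)
  expect_equal(am$mode, "current-frames")
  neg <- adult_mass(42, 20, 22.3)
  expect_equal(neg$kg, 0)
  expect_true(neg$negative_flag)
  st <- adult_mass(45, 20)
  expect_equal(st$kg, 25)
  expect_equal(st$mode, "start-tare-only")
})
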