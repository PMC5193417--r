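# Censored Weibull survivorship and bee-day accounting.

test_that("expansion to individuals conserves n0 and applies the time
           conventions", {
  tr <- cage_trial("c1", 0, n0 = 5,
                   deaths = data.frame(day = 2, n = 2),
                   censored = data.frame(day = 4, n = 3))
  rec <- expand_to_individuals(tr)
  expect_equal(nrow(rec), 5L)
  expect_equal(sort(rec$time[rec$status == 1]), c(1.5, 1.5))  # day midpoints
  expect_equal(rec$time[rec$status == 0], c(4, 4, 4))
  recd <- expand_to_individuals(tr, death_time = "day")
  expect_equal(sort(recd$time[recd$status == 1]), c(2, 2))
  # survivors are censored at the termination day
  tr2 <- cage_trial("c2", 0, n0 = 10, deaths = data.frame(day = 3, n = 1))
  rec2 <- expand_to_individuals(tr2, final_day = 50)
  expect_equal(sum(rec2$status == 0 & rec2$time == 50), 9L)
  expect_error(cage_trial("c3", 0, n0 = 4, deaths = data.frame(day = 1, n = 5)),
               "exceed")
})

test_that("the standard censoring pattern conserves every bee", {
  g <- gen_cage_trial(cage_scenario(seed = 5, treatments = data.frame(
    ppb = 0, mu = log(40), sigma = 0.3, consumption_mg_bee_day = 20),
    n_cages = 3))
  for (tr in g$trials) {
    rec <- expand_to_individuals(tr, final_day = 50)
    expect_equal(nrow(rec), 100L)
    expect_equal(sum(tr$deaths$n) + sum(rec$status == 0), 100L)
  }
})

test_that("Weibull fits agree with a direct maximum-likelihood oracle", {
  set.seed(42)
  tt <- exp(log(40) + 0.3 * log(-log(runif(80))))
  st <- as.integer(tt < 45)
  rec <- data.frame(time = pmin(tt, 45), status = st)
  f <- fit_weibull(rec)
  o <- weibull_ml_oracle(rec)
  expect_equal(f$mu, o$mu, tolerance = 1e-4)
  expect_equal(f$sigma, o$sigma, tolerance = 1e-4)
  expect_equal(f$se_mu, o$se_mu, tolerance = 1e-3)
  # closed-form percentiles from the fitted parameters
  expect_equal(unname(f$percentiles["p50"]),
               exp(f$mu + f$sigma * log(log(2))))
  expect_true(all(diff(weibull_percentile(f, c(0.3, 0.4, 0.5))) > 0))
})

test_that("fitting refuses degenerate mortality data", {
  all_cens <- data.frame(time = rep(50, 20), status = 0L)
  expect_true(is_nofit(fit_weibull(all_cens)))
  one_day <- data.frame(time = c(rep(10, 5), rep(50, 15)),
                        status = c(rep(1L, 5), rep(0L, 15)))
  expect_true(is_nofit(fit_weibull(one_day)))
})

test_that("AFT equivariance: scaling time shifts mu by log k and leaves
           sigma unchanged", {
  set.seed(9)
  tt <- exp(log(30) + 0.25 * log(-log(runif(60))))
  rec <- data.frame(time = tt, status = 1L)
  f1 <- fit_weibull(rec)
  f3 <- fit_weibull(transform(rec, time = time * 3))
  expect_equal(f3$mu - f1$mu, log(3), tolerance = 1e-6)
  expect_equal(f3$sigma, f1$sigma, tolerance = 1e-6)
  expect_equal(shape_stat(f3)$value, 3 * shape_stat(f1)$value,
               tolerance = 1e-5)
})

test_that("the shape statistic matches closed forms in both conventions", {
  # exponential case (mu = 0, sigma = 1): percentiles are -log(1 - p)
  f <- structure(list(mu = 0, sigma = 1), class = "hb_weibull_fit")
  ss <- shape_stat(f)
  expect_equal(ss$value, -log(0.7) - (-log(0.6)), tolerance = 1e-9)
  expect_equal(ss$value, -0.1541507, tolerance = 1e-6)
  expect_lt(ss$value, 0)  # CDF time percentiles: p30 <= p40
  sv <- shape_stat(f, "survivor")
  expect_equal(sv$value, -log(0.3) - (-log(0.4)), tolerance = 1e-9)
  expect_gt(sv$value, 0)
  # degenerate distribution: shape difference collapses to zero
  fd <- structure(list(mu = log(40), sigma = 1e-8), class = "hb_weibull_fit")
  expect_equal(shape_stat(fd)$value, 0, tolerance = 1e-6)
})

test_that("heavy censoring inflates standard errors on the same data", {
  set.seed(31)
  tt <- exp(log(40) + 0.3 * log(-log(runif(100))))
  full <- data.frame(time = tt, status = 1L)
  cut <- quantile(tt, 0.2)
  cens <- data.frame(time = pmin(tt, cut), status = as.integer(tt <= cut))
  f_full <- fit_weibull(full)
  f_cens <- fit_weibull(cens)
  expect_gt(f_cens$se_mu, f_full$se_mu)
})

test_that("bee-days follow the daily-check convention and match per-bee
           enumeration", {
  none <- cage_trial("c", 0, n0 = 100)
  expect_equal(bee_days(none, c(1, 7)), 700)
  one <- cage_trial("c", 0, n0 = 2, deaths = data.frame(day = 1, n = 1))
  expect_equal(bee_days(one, c(1, 2)), 3)          # default convention
  expect_equal(bee_days(one, c(1, 2), 0.5), 2.5)
  expect_equal(bee_days(one, c(1, 2), 0), 2)
  for (seed in 1:30) {
    tr <- random_trial(seed)
    iv <- sort(sample(1:20, 2))
    for (w in c(0, 0.5, 1))
      expect_equal(bee_days(tr, iv, w), bee_days_enum(tr, iv, w))
  }
})

test_that("consumption per bee-day divides grams by bee-days", {
  tr <- cage_trial("c", 0, n0 = 100,
                   syrup = data.frame(start_day = 1, end_day = 7, grams = 14))
  expect_equal(consumption_per_bee(tr, c(1, 7)), 20)
  tr0 <- cage_trial("c", 0, n0 = 100,
                    syrup = data.frame(start_day = 1, end_day = 7, grams = 0))
  expect_equal(consumption_per_bee(tr0, c(1, 7)), 0)
  expect_error(consumption_per_bee(tr, c(2, 8)), "no syrup weighing")
  # zero bee-days: undefined with a warning
  dead <- cage_trial("c", 0, n0 = 2, deaths = data.frame(day = 1, n = 2),
                     syrup = data.frame(start_day = 3, end_day = 4, grams = 1))
  expect_warning(val <- consumption_per_bee(dead, c(3, 4)), "zero bee-days")
  expect_true(is.na(val))
})

test_that("generated consumption round-trips through the estimator exactly", {
  g <- gen_cage_trial(cage_scenario(seed = 2, treatments = data.frame(
    ppb = 0, mu = log(40), sigma = 0.3, consumption_mg_bee_day = 22.6),
    n_cages = 2))
  for (tr in g$trials) {
    for (r in seq_len(nrow(tr$syrup))) {
      iv <- c(tr$syrup$start_day[r], tr$syrup$end_day[r])
      expect_equal(consumption_per_bee(tr, iv), 22.6, tolerance = 1e-9)
    }
  }
})
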