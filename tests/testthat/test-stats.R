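# Treatment-comparison layer.

test_that("identical groups give a null F and a single letter", {
  y <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  r <- ancova(y, g)
  expect_equal(r$F, 0, tolerance = 1e-12)
  expect_true(all(r$letters == r$letters[1]))
  expect_equal(nrow(r$contrasts), 1L)
})

test_that("Bonferroni adjustment multiplies raw p by the number of pairs", {
  set.seed(4)
  y <- rnorm(16)
  g <- rep(letters[1:4], each = 4)
  r <- ancova(y, g)
  expect_equal(nrow(r$contrasts), 6L)
  expect_equal(r$contrasts$p_adj, pmin(1, 6 * r$contrasts$p_raw))
  expect_true(all(r$contrasts$p_adj >= r$contrasts$p_raw))
})

test_that("known covariate slope and group effect are recovered", {
  set.seed(12)
  hits <- 0L
  slopes_ok <- 0L
  for (i in 1:200) {
    g <- rep(letters[1:3], each = 4)
    x <- rnorm(12)
    eff <- c(a = 0, b = 2, c = 4)[g]
    y <- 1 + 1.0 * x + eff + rnorm(12, 0, 0.1)
    r <- ancova(y, g, covariate = x)
    if (!is.na(r$p) && r$p < 0.05) hits <- hits + 1L
    if (abs(r$covariate_slope - 1.0) < 3 * r$covariate_slope_se)
      slopes_ok <- slopes_ok + 1L
  }
  expect_gte(hits / 200, 0.95)
  expect_gte(slopes_ok / 200, 0.95)
})

test_that("rank test matches hand computation and degenerates gracefully", {
  r <- kruskal_wallis_groups(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$H, 3.857143, tolerance = 1e-6)
  expect_equal(r$df, 1L)
  same <- kruskal_wallis_groups(list(rep(2, 4), rep(2, 4)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  # H depends on the rank pattern, not the group labels
  a <- kruskal_wallis_groups(list(c(1, 5, 9), c(2, 6, 10)))
  b <- kruskal_wallis_groups(list(c(2, 6, 10), c(1, 5, 9)))
  expect_equal(a$H, b$H)
})

test_that("letter displays round-trip the significant-pair decisions", {
  set.seed(7)
  for (ng in c(3, 4, 5, 6)) {
    groups <- letters[seq_len(ng)]
    pairs <- t(combn(groups, 2))
    for (rep in 1:20) {
      sig <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
      disp <- hivebeat:::letter_display(
        groups, data.frame(group1 = sig[, 1], group2 = sig[, 2]))
      share <- function(i, j) {
        li <- strsplit(disp[[i]], "")[[1]]
        lj <- strsplit(disp[[j]], "")[[1]]
        length(intersect(li, lj)) > 0
      }
      for (k in seq_len(nrow(pairs))) {
        is_sig <- any(sig[, 1] == pairs[k, 1] & sig[, 2] == pairs[k, 2])
        expect_identical(!share(pairs[k, 1], pairs[k, 2]), is_sig,
                         label = sprintf("ng=%d rep=%d pair=%s-%s", ng, rep,
                                         pairs[k, 1], pairs[k, 2]))
      }
    }
  }
})

test_that("period-wise comparison localises a period-2-only group effect", {
  set.seed(5)
  design <- treatment_design("SYN", paste0("h", 1:12),
                             rep(c(0, 5, 100), each = 4))
  days <- as.Date("2014-07-01") + seq(0, 39, by = 5)
  mk <- function() {
    do.call(rbind, lapply(paste0("h", 1:12), function(hid) {
      dose <- design$imidacloprid_ppb[design$hive_id == hid]
      eff <- ifelse(days >= as.Date("2014-07-21") & dose == 100, 2, 0)
      data.frame(hive_id = hid, day = days, value = 1 + eff + rnorm(length(days), 0, 0.1))
    }))
  }
  periods <- data.frame(label = c("pre", "during"),
                        start_day = as.Date(c("2014-07-01", "2014-07-21")),
                        end_day = as.Date(c("2014-07-20", "2014-08-09")))
  res <- rm_group_time(mk(), design, periods)
  expect_named(res$results, c("pre", "during"))
  expect_gt(res$results$pre$p, 0.05)
  expect_lt(res$results$during$p, 0.05)
  expect_match(res$note, "simplification")
})

test_that("a single period reduces exactly to one ANCOVA", {
  set.seed(6)
  design <- treatment_design("SYN", paste0("h", 1:8), rep(c(0, 100), each = 4))
  days <- as.Date("2014-07-01") + 0:4
  dat <- do.call(rbind, lapply(paste0("h", 1:8), function(hid)
    data.frame(hive_id = hid, day = days, value = rnorm(5))))
  periods <- data.frame(label = "all", start_day = min(days), end_day = max(days))
  res <- rm_group_time(dat, design, periods)
  agg <- aggregate(value ~ hive_id, dat, mean)
  agg <- merge(agg, design[, c("hive_id", "group")], by = "hive_id")
  direct <- ancova(agg$value, agg$group)
  expect_equal(res$results$all$F, direct$F)
  expect_equal(res$results$all$p, direct$p)
})

test_that("overlapping periods are refused and thin groups skipped", {
  design <- treatment_design("SYN", paste0("h", 1:4), rep(c(0, 100), each = 2))
  dat <- data.frame(hive_id = rep(paste0("h", 1:4), each = 2),
                    day = as.Date("2014-07-01") + c(0, 10), value = rnorm(8))
  bad <- data.frame(label = c("p1", "p2"),
                    start_day = as.Date(c("2014-07-01", "2014-07-05")),
                    end_day = as.Date(c("2014-07-06", "2014-07-12")))
  expect_error(rm_group_time(dat, design, bad), "overlap")
  # a period in which one group has < 2 hives is skipped with a reason
  dat2 <- dat[!(dat$hive_id %in% c("h3", "h4") & dat$day == as.Date("2014-07-01")), ]
  periods <- data.frame(label = c("p1", "p2"),
                        start_day = as.Date(c("2014-07-01", "2014-07-07")),
                        end_day = as.Date(c("2014-07-03", "2014-07-12")))
  res <- rm_group_time(dat2, design, periods)
  expect_equal(res$skipped$label, "p1")
  expect_match(res$skipped$reason, "fewer than 2")
})
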