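# Treatment-comparison layer: covariate-adjusted ANOVA (ANCOVA) with
# Bonferroni post hoc contrasts and letter displays, nonparametric group
# tests, and grouped period-wise repeated-measures summaries.
#
# The field-trial inference pattern is period-wise: responses are summarised
# per hive within pre-treatment / during-treatment / post-treatment windows
# and compared across treatment groups with pre-treatment values (or adult
# bee mass) as covariates. Multivariate repeated-measures machinery is
# deliberately out of scope; the per-period simplification is stamped into
# the output metadata.

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Fits `response ~ covariate + group` (or `response ~ group` without a
#' covariate), reports the F test for the group factor (sequential, group
#' after covariate), covariate-adjusted group means, all pairwise contrasts
#' with Bonferroni adjustment (`m` = number of pairs, adjusted
#' `p = min(1, m * raw)`), and a compact letter display in which groups
#' sharing no letter differ at `alpha`.
#'
#' @param response Numeric response, one value per experimental unit (hive).
#' @param group Group labels (coerced to factor); >= 2 groups with >= 2
#'   units each.
#' @param covariate Optional numeric covariate (e.g. the pre-treatment value
#'   of the response, or adult bee mass).
#' @param alpha Significance level for the letter display (default 0.05).
#' @param label Optional response/period label carried into the result.
#' @return A list of class `hb_comparison`: `response`, `period`,
#'   `F`, `df`, `p`, `means` (group, emmean, se), `contrasts` (group1,
#'   group2, estimate, p_raw, p_adj), `letters` (named character),
#'   `alpha`, `covariate_slope` (NA if none), `note`.
#' @export
ancova <- function(response, group, covariate = NULL, alpha = 0.05,
                   label = "response") {
  group <- factor(group)
  if (nlevels(group) < 2L) stopf("need >= 2 groups")
  if (any(table(group) < 2L)) stopf("need >= 2 replicates per group")
  dat <- data.frame(y = response, g = group)
  has_cov <- !is.null(covariate)
  if (has_cov) dat$x <- covariate
  fml <- if (has_cov) y ~ x + g else y ~ g
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < length(coef(fit)))
    stopf("rank-deficient model: check group/covariate coding")
  an <- stats::anova(fit)
  Fg <- an["g", "F value"]
  p <- an["g", "Pr(>F)"]
  dfs <- c(an["g", "Df"], an["Residuals", "Df"])
  em <- emmeans::emmeans(fit, "g")
  means <- as.data.frame(em)[, c("g", "emmean", "SE")]
  names(means) <- c("group", "emmean", "se")
  ctr_raw <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  m <- nrow(ctr_raw)
  sides <- do.call(rbind, strsplit(as.character(ctr_raw$contrast), " - "))
  contrasts <- data.frame(group1 = sides[, 1], group2 = sides[, 2],
                          estimate = ctr_raw$estimate,
                          p_raw = ctr_raw$p.value,
                          p_adj = pmin(1, m * ctr_raw$p.value),
                          stringsAsFactors = FALSE)
  sig <- !is.na(contrasts$p_adj) & contrasts$p_adj < alpha
  letters <- letter_display(levels(group),
                            contrasts[sig, c("group1", "group2"), drop = FALSE])
  structure(list(
    response = label, period = NA_character_,
    F = Fg, df = dfs, p = p, means = means, contrasts = contrasts,
    letters = letters, alpha = alpha,
    covariate_slope = if (has_cov) unname(coef(fit)["x"]) else NA_real_,
    covariate_slope_se = if (has_cov)
      sqrt(diag(vcov(fit)))[["x"]] else NA_real_,
    note = "one-way ANCOVA; Bonferroni-adjusted pairwise contrasts"),
    class = "hb_comparison")
}

#' @export
print.hb_comparison <- function(x, ...) {
  cat(sprintf("<group comparison> %s%s: F(%d,%d) = %.3f, p = %.4g\n",
              x$response,
              if (is.na(x$period)) "" else paste0(" [", x$period, "]"),
              x$df[1], x$df[2], x$F, x$p))
  disp <- x$means
  disp$letters <- x$letters[as.character(disp$group)]
  print(disp, row.names = FALSE)
  invisible(x)
}

# Compact letter display by insert-and-absorb: start from one set holding
# all groups; each significantly different pair splits every set containing
# both; sets contained in another are absorbed. Groups sharing no letter
# are exactly the significant pairs.
letter_display <- function(groups, sig_pairs) {
  sets <- list(groups)
  if (nrow(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      a <- as.character(sig_pairs$group1[r]); b <- as.character(sig_pairs$group2[r])
      new_sets <- list()
      for (s in sets) {
        if (a %in% s && b %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else new_sets <- c(new_sets, list(s))
      }
      # absorb duplicates and proper subsets
      new_sets <- unique(lapply(new_sets[lengths(new_sets) > 0], sort))
      keep <- vapply(seq_along(new_sets), function(i) {
        !any(vapply(seq_along(new_sets), function(j) {
          j != i && length(new_sets[[i]]) < length(new_sets[[j]]) &&
            all(new_sets[[i]] %in% new_sets[[j]])
        }, logical(1)))
      }, logical(1))
      sets <- new_sets[keep]
    }
  }
  ord <- order(vapply(sets, function(s) min(match(s, groups)), numeric(1)))
  sets <- sets[ord]
  out <- setNames(rep("", length(groups)), groups)
  for (k in seq_along(sets))
    out[sets[[k]]] <- paste0(out[sets[[k]]], letters[k])
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based H statistic with tie correction and a chi-square reference
#' distribution (via [stats::kruskal.test()]). The fully degenerate case --
#' every observation identical -- is reported as `H = 0, p = 1` rather than
#' the undefined tie-corrected ratio.
#'
#' @param values_by_group A named list of numeric vectors, one per group.
#' @return List: `H`, `df`, `p`.
#' @export
kruskal_wallis_groups <- function(values_by_group) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2L)
  allv <- unlist(values_by_group, use.names = FALSE)
  if (length(unique(allv)) == 1L)
    return(list(H = 0, df = length(values_by_group) - 1L, p = 1))
  kt <- stats::kruskal.test(values_by_group)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Period-wise group comparison of a repeated hive-level series
#'
#' Approximates a repeated-measures group x time analysis by summarising
#' the (thinned, non-overlapping) per-hive series within each period window
#' as a hive-level mean and running [ancova()] per period. A single period
#' reduces exactly to one ANCOVA. Periods must not overlap; periods with
#' fewer than 2 hives in any group are skipped with the reason recorded.
#'
#' @param data Data.frame `hive_id, day, value` (e.g. a thinned
#'   [amplitude_series()] with `value = amplitude`).
#' @param design An [treatment_design()] (uses `hive_id`, `group`).
#' @param periods Data.frame `label, start_day, end_day` (Dates, inclusive).
#' @param covariate Optional named numeric vector, names = hive ids (e.g.
#'   adult bee mass).
#' @param alpha Significance level (default 0.05).
#' @return List of class `hb_rm_comparison`: `results` (one
#'   `hb_comparison` per analysed period), `skipped` (data.frame label,
#'   reason), `note` stamping the repeated-measures simplification.
#' @export
rm_group_time <- function(data, design, periods, covariate = NULL,
                          alpha = 0.05) {
  stopifnot(all(c("hive_id", "day", "value") %in% names(data)),
            all(c("label", "start_day", "end_day") %in% names(periods)))
  periods <- periods[order(periods$start_day), , drop = FALSE]
  if (any(periods$end_day < periods$start_day))
    stopf("period end before start")
  if (nrow(periods) > 1L &&
      any(periods$start_day[-1] <= periods$end_day[-nrow(periods)]))
    stopf("period windows overlap")
  results <- list()
  skipped <- data.frame(label = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrow(periods))) {
    lab <- periods$label[r]
    sel <- data$day >= periods$start_day[r] & data$day <= periods$end_day[r]
    if (!any(sel)) {
      skipped <- rbind(skipped, data.frame(label = lab, reason = "no data in period"))
      next
    }
    agg <- stats::aggregate(value ~ hive_id, data = data[sel, ], FUN = mean)
    agg <- merge(agg, design[, c("hive_id", "group")], by = "hive_id")
    tab <- table(agg$group)
    if (length(tab) < 2L || any(tab < 2L)) {
      skipped <- rbind(skipped, data.frame(
        label = lab, reason = "fewer than 2 hives in some group"))
      next
    }
    cov <- if (is.null(covariate)) NULL else unname(covariate[agg$hive_id])
    cmp <- ancova(agg$value, agg$group, covariate = cov, alpha = alpha,
                  label = lab)
    cmp$period <- lab
    results[[lab]] <- cmp
  }
  structure(list(results = results, skipped = skipped,
                 note = paste("per-period ANCOVA on hive-level means;",
                              "repeated-measures simplification")),
            class = "hb_rm_comparison")
}

#' @export
print.hb_rm_comparison <- function(x, ...) {
  cat(sprintf("<period-wise comparison> %d period(s) analysed, %d skipped\n",
              length(x$results), nrow(x$skipped)))
  for (r in x$results) print(r)
  if (nrow(x$skipped)) print(x$skipped, row.names = FALSE)
  invisible(x)
}
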