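#' Longitudinal group statistics
#'
#' The study layer that turns per-vessel measurements into group-level
#' trajectories: per-group per-timepoint mean and standard deviation,
#' range-normalization with mean-centering for plotting indices of different
#' units on one axis, and per-timepoint paired Student's t-tests of each
#' follow-up timepoint against the pre-surgery baseline at significance level
#' alpha = 0.1.
#'
#' @name stats-layer
NULL

#' Per-group per-timepoint mean and standard deviation
#'
#' @param table data.frame with columns `group`, `subject_id`, `timepoint_h`,
#'   `quantity`, `value` (the layout produced by [simulate_cohort()] and the
#'   pipeline's results).
#' @param quantity which quantity to summarize.
#' @return data.frame `group`, `timepoint_h`, `mean`, `sd` (n-1 denominator;
#'   `NA` for a single subject), `n`.
#' @export
group_summary <- function(table, quantity) {
  tab <- table[table$quantity == quantity, , drop = FALSE]
  if (nrow(tab) == 0L) stop_mf("no records for quantity '%s'", quantity)
  agg <- stats::aggregate(value ~ group + timepoint_h, data = tab,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(group = agg$group, timepoint_h = agg$timepoint_h,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n = as.integer(agg$value[, "n"]))
  out[order(out$group, out$timepoint_h), , drop = FALSE]
}

#' Normalize and centralize a series
#'
#' Puts indices of different units on a common dimensionless axis:
#' `x -> (x - mean(x)) / (max(x) - min(x))`. The output has mean 0 and range
#' exactly 1, and is invariant to positive affine transforms of the input.
#' `mode = "zscore"` offers `(x - mean) / sd` as an alternative reading of
#' "normalized and centralized"; the range rule is the default.
#'
#' @param x numeric series (per-timepoint means of one group/quantity);
#'   must be non-constant.
#' @param mode "range" (default) or "zscore".
#' @return transformed numeric vector.
#' @export
normalize_centralize <- function(x, mode = c("range", "zscore")) {
  mode <- match.arg(mode)
  if (!is.numeric(x) || length(x) < 2L) stop_mf("x must be a numeric series")
  rng <- max(x) - min(x)
  if (rng == 0) stop_mf("zero range: constant series cannot be normalized")
  if (mode == "range") (x - mean(x)) / rng
  else (x - mean(x)) / stats::sd(x)
}

#' Paired t-test of one timepoint against baseline
#'
#' Two-sided paired Student's t on the per-subject differences
#' (timepoint - baseline), p from the t distribution with n - 1 df, flagged
#' significant when p < alpha. The paired form reflects the design: the same
#' subjects are measured at baseline and follow-up. Zero-variance
#' differences are handled explicitly: all-zero differences give p = 1
#' (flag 0); constant non-zero differences give p = 0 (flag 1).
#' `paired = FALSE` switches to Welch's two-sample test.
#'
#' @param table longitudinal data.frame (see [group_summary()]).
#' @param group group to test.
#' @param quantity quantity to test.
#' @param timepoint follow-up timepoint.
#' @param baseline baseline timepoint.
#' @param alpha significance level (default 0.1).
#' @param paired paired (default) or Welch unpaired.
#' @return list `t`, `p`, `flag` (1 iff p < alpha), `df`, `n`.
#' @export
ttest_vs_baseline <- function(table, group, quantity, timepoint, baseline,
                              alpha = 0.1, paired = TRUE) {
  assert_scalar_num(alpha, "alpha", 0, 1)
  tab <- table[table$group == group & table$quantity == quantity, ,
               drop = FALSE]
  b <- tab[tab$timepoint_h == baseline, c("subject_id", "value")]
  f <- tab[tab$timepoint_h == timepoint, c("subject_id", "value")]
  mm <- merge(b, f, by = "subject_id", suffixes = c("_base", "_follow"))
  n <- nrow(mm)
  if (n < 2L)
    stop_mf("need >= 2 paired subjects (got %d) for group '%s' at t = %s",
            n, group, format(timepoint))
  if (paired) {
    d <- mm$value_follow - mm$value_base
    if (stats::sd(d) == 0) {
      if (all(d == 0)) return(list(t = 0, p = 1, flag = 0L,
                                   df = n - 1L, n = n))
      return(list(t = sign(mean(d)) * Inf, p = 0, flag = as.integer(0 < alpha),
                  df = n - 1L, n = n))
    }
    ht <- stats::t.test(d)
  } else {
    if (stats::sd(mm$value_follow) == 0 && stats::sd(mm$value_base) == 0) {
      same <- mean(mm$value_follow) == mean(mm$value_base)
      return(list(t = if (same) 0 else Inf, p = if (same) 1 else 0,
                  flag = as.integer(!same && 0 < alpha), df = n - 1L, n = n))
    }
    ht <- stats::t.test(mm$value_follow, mm$value_base)
  }
  p <- ht$p.value
  list(t = unname(ht$statistic), p = p, flag = as.integer(p < alpha),
       df = unname(ht$parameter), n = n)
}

#' Significance timeline against baseline
#'
#' Runs [ttest_vs_baseline()] at every timepoint after (or other than) the
#' baseline and reports the 0/1 existence-of-difference flags.
#'
#' @inheritParams ttest_vs_baseline
#' @return data.frame `timepoint_h`, `t`, `p`, `flag`, plus attribute
#'   `alpha`.
#' @export
significance_timeline <- function(table, group, quantity, baseline,
                                  alpha = 0.1, paired = TRUE) {
  tps <- sort(unique(table$timepoint_h[table$group == group &
                                         table$quantity == quantity]))
  tps <- tps[tps != baseline]
  rows <- lapply(tps, function(tp) {
    r <- ttest_vs_baseline(table, group, quantity, tp, baseline, alpha,
                           paired)
    data.frame(timepoint_h = tp, t = r$t, p = r$p, flag = r$flag)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}
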