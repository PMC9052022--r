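# Descriptive summaries, the Wilcoxon signed-rank test (exact and
# tie-corrected normal approximation), and the effect tables.

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7) by default; the convention is a parameter
#' because statistical packages disagree across versions.
#'
#' @param values Nonempty numeric vector (`NA`s are not accepted).
#' @param quantile_type Quantile algorithm (see [stats::quantile()]).
#' @return List with `median`, `q1`, `q3`, `n`.
#' @export
median_iqr <- function(values, quantile_type = 7) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop("median_iqr: empty input, summary undefined", call. = FALSE)
  }
  if (anyNA(values)) stop("median_iqr: NA values in input", call. = FALSE)
  q <- quantile(values, c(0.25, 0.5, 0.75), type = quantile_type,
                names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], n = length(values))
}

# Exact null distribution of W (sum of positive signed ranks) by
# shift-convolution. Average ranks are multiples of 1/2, so doubling makes
# them integers; counts stay exact in doubles up to 2^53.
.signed_rank_exact_p <- function(W, r) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1L) # counts[s + 1] = #assignments with sum s
  counts[1L] <- 1
  for (ri in r2) {
    idx <- seq_len(total - ri + 1L)
    counts[idx + ri] <- counts[idx + ri] + counts[idx]
  }
  s <- 0:total
  mu <- total / 2
  dev <- abs(2 * W - mu)
  p <- sum(counts[abs(s - mu) >= dev - 1e-9]) / 2^length(r2)
  min(1, p)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Tests whether paired differences `after - before` are symmetric about
#' zero. Zero differences are dropped (the classic zero-discard rule;
#' `n_effective` counts the nonzero differences), absolute differences are
#' ranked with average ranks for ties, and the statistic is
#' `W = sum of ranks of positive differences`. The exact two-sided p-value
#' enumerates the null distribution of W over all sign assignments (computed
#' by convolution; valid with ties) when `n_effective <= exact_cutoff` in
#' `"auto"` mode; otherwise a normal approximation with tie-corrected
#' variance (`sum(r^2)/4`) and continuity correction is used. Two-sided
#' p-values throughout, clipped to \[0, 1\].
#'
#' @param before,after Equal-length paired numeric vectors.
#' @param mode `"auto"` (exact up to the cutoff), `"exact"`, or
#'   `"approximate"`.
#' @param exact_cutoff Largest `n_effective` for which `"auto"` uses the
#'   exact distribution (default 25).
#' @param correct Apply the continuity correction in the approximation.
#' @return List: `statistic` (W), `p_value`, `n_effective`, `method`
#'   (`"exact"`, `"approximate"` or `"degenerate"`), `degenerate` (`TRUE`
#'   when all differences are zero, giving W = 0 and p = 1).
#' @examples
#' wilcoxon_signed_rank(rep(0, 5), 1:5) # W = 15, exact p = 0.0625
#' @export
wilcoxon_signed_rank <- function(before, after,
                                 mode = c("auto", "exact", "approximate"),
                                 exact_cutoff = 25, correct = TRUE) {
  mode <- match.arg(mode)
  if (length(before) != length(after)) {
    stop("before and after must have equal length", call. = FALSE)
  }
  d <- as.numeric(after) - as.numeric(before)
  if (anyNA(d)) stop("NA in paired differences", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  use_exact <- mode == "exact" || (mode == "auto" && n <= exact_cutoff)
  if (use_exact) {
    p <- .signed_rank_exact_p(W, r)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2)) / 2
    z <- W - mu
    cc <- if (correct) sign(z) * 0.5 else 0
    p <- if (sigma == 0) 1 else min(1, 2 * pnorm(-abs((z - cc) / sigma)))
    method <- "approximate"
  }
  list(statistic = W, p_value = p, n_effective = n, method = method,
       degenerate = FALSE)
}

#' Significance tier of a p-value
#'
#' Maps p-values to the reporting tiers `P<.001`, `P<.01`, `P<.05` and `ns`
#' (alpha = .05; no multiple-testing correction, mirroring the reporting
#' convention of the analysis).
#'
#' @param p Numeric p-values.
#' @return Character vector of tiers (`NA` for `NA` input).
#' @export
significance_tier <- function(p) {
  out <- rep(NA_character_, length(p))
  out[!is.na(p)] <- "ns"
  out[!is.na(p) & p < 0.05] <- "P<.05"
  out[!is.na(p) & p < 0.01] <- "P<.01"
  out[!is.na(p) & p < 0.001] <- "P<.001"
  out
}

#' Immediate-effect table: before vs after medians with signed-rank tests
#'
#' One row per metric (in the supplied order): median and IQR of the before
#' and after window means over the tested pairs, the signed-rank statistic,
#' two-sided p-value and significance tier. Descriptives are computed on
#' exactly the pairs entering the test. A metric with zero pairs yields a row
#' of `NA` statistics.
#'
#' @param pairs Long pair table from [build_before_after()].
#' @param metrics Ordered metric list (default [activity_metrics]).
#' @param mode,exact_cutoff Passed to [wilcoxon_signed_rank()].
#' @param quantile_type Quartile convention for the descriptives.
#' @return data.table: `metric`, `n_pairs`, `before_median`, `before_q1`,
#'   `before_q3`, `after_median`, `after_q1`, `after_q3`, `w_statistic`,
#'   `p_value`, `tier`.
#' @export
immediate_effect_table <- function(pairs, metrics = activity_metrics,
                                   mode = "auto", exact_cutoff = 25,
                                   quantile_type = 7) {
  p <- as.data.table(pairs)
  rows <- lapply(metrics, function(m) {
    sub <- p[metric == m]
    if (nrow(sub) == 0L) {
      return(data.table(metric = m, n_pairs = 0L,
                        before_median = NA_real_, before_q1 = NA_real_,
                        before_q3 = NA_real_, after_median = NA_real_,
                        after_q1 = NA_real_, after_q3 = NA_real_,
                        w_statistic = NA_real_, p_value = NA_real_,
                        tier = NA_character_))
    }
    b <- median_iqr(sub$before, quantile_type)
    a <- median_iqr(sub$after, quantile_type)
    t <- wilcoxon_signed_rank(sub$before, sub$after, mode = mode,
                              exact_cutoff = exact_cutoff)
    data.table(metric = m, n_pairs = nrow(sub),
               before_median = b$median, before_q1 = b$q1, before_q3 = b$q3,
               after_median = a$median, after_q1 = a$q1, after_q3 = a$q3,
               w_statistic = t$statistic, p_value = t$p_value,
               tier = significance_tier(t$p_value))
  })
  rbindlist(rows)
}

#' Per-participant averaged sensitivity analysis
#'
#' Some participants contribute several visits, hence several paired
#' observations. As a sensitivity analysis, each participant's before-values
#' and after-values are averaged within metric (and module) first, so every
#' participant contributes one pair, and the immediate-effect table is
#' recomputed on those.
#'
#' @inheritParams immediate_effect_table
#' @return As [immediate_effect_table()], with `n_pairs` counting
#'   participants.
#' @export
per_participant_sensitivity <- function(pairs, metrics = activity_metrics,
                                        mode = "auto", exact_cutoff = 25,
                                        quantile_type = 7) {
  p <- as.data.table(pairs)
  agg <- p[, .(before = mean(before), after = mean(after)),
           by = .(participant_id, module_id, metric)]
  immediate_effect_table(agg, metrics = metrics, mode = mode,
                         exact_cutoff = exact_cutoff,
                         quantile_type = quantile_type)
}

#' Sustained-effect table over eight post-visit weeks
#'
#' For each metric, the before-window row pools every visit with a defined
#' before-window; each week-k row summarises the visits with a defined
#' week-k window and reports the signed-rank test of week k against before,
#' computed on the visits where both windows are defined.
#'
#' @param weekly Window table from [weekly_windows()] (complete visits).
#' @param metrics Metric columns (default the active-minute categories).
#' @param mode,exact_cutoff Passed to [wilcoxon_signed_rank()].
#' @param quantile_type Quartile convention.
#' @return data.table: `metric`, `window` (`"before"`, `"week1"`, ...),
#'   `n`, `median`, `q1`, `q3`, `w_statistic`, `p_value`, `tier` (test
#'   columns `NA` for the before row; a window with no defined visits yields
#'   `n = 0` and `NA` summaries).
#' @export
sustained_effect_table <- function(weekly, metrics = active_minute_metrics,
                                   mode = "auto", exact_cutoff = 25,
                                   quantile_type = 7) {
  w <- as.data.table(weekly)
  keys <- c("participant_id", "module_id", "visit_index")
  labels <- unique(w$window_label)
  week_labels <- setdiff(labels, "before")
  bef <- w[window_label == "before"]
  rows <- list()
  for (m in metrics) {
    bvals <- bef[[m]]
    bdef <- !is.na(bvals)
    desc <- if (any(bdef)) median_iqr(bvals[bdef], quantile_type) else
      list(median = NA_real_, q1 = NA_real_, q3 = NA_real_, n = 0L)
    rows[[length(rows) + 1L]] <- data.table(
      metric = m, window = "before", n = sum(bdef),
      median = desc$median, q1 = desc$q1, q3 = desc$q3,
      w_statistic = NA_real_, p_value = NA_real_, tier = NA_character_)
    for (lbl in week_labels) {
      wk <- w[window_label == lbl]
      # align week rows with before rows by visit
      merged <- merge(bef[, c(keys, m), with = FALSE],
                      wk[, c(keys, m), with = FALSE],
                      by = keys, suffixes = c(".before", ".week"))
      bv <- merged[[paste0(m, ".before")]]
      wv <- merged[[paste0(m, ".week")]]
      wdef <- !is.na(wk[[m]])
      if (!any(wdef)) {
        rows[[length(rows) + 1L]] <- data.table(
          metric = m, window = lbl, n = 0L, median = NA_real_,
          q1 = NA_real_, q3 = NA_real_, w_statistic = NA_real_,
          p_value = NA_real_, tier = NA_character_)
        next
      }
      desc_w <- median_iqr(wk[[m]][wdef], quantile_type)
      both <- !is.na(bv) & !is.na(wv)
      if (any(both)) {
        t <- wilcoxon_signed_rank(bv[both], wv[both], mode = mode,
                                  exact_cutoff = exact_cutoff)
        tst <- list(w = t$statistic, p = t$p_value)
      } else {
        tst <- list(w = NA_real_, p = NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.table(
        metric = m, window = lbl, n = sum(wdef),
        median = desc_w$median, q1 = desc_w$q1, q3 = desc_w$q3,
        w_statistic = tst$w, p_value = tst$p,
        tier = significance_tier(tst$p))
    }
  }
  rbindlist(rows)
}

#' Render an effect table in the familiar "median (q1-q3)" layout
#'
#' Formats an immediate-effect or sustained-effect table for reading, with
#' medians and quartiles rounded to one decimal (steps and energy to the
#' nearest integer) and significance tiers appended. Full precision is kept
#' in the underlying tables; rounding here is display only.
#'
#' @param tab Output of [immediate_effect_table()] or
#'   [sustained_effect_table()].
#' @return data.frame of formatted strings.
#' @export
render_effect_table <- function(tab) {
  t <- as.data.table(tab)
  fmt1 <- function(med, q1, q3, metric) {
    digits <- ifelse(metric %in% c("steps", "energy_kcal"), 0L, 1L)
    ifelse(is.na(med), "-",
           sprintf("%.*f (%.*f-%.*f)", digits, med, digits, q1, digits, q3))
  }
  fmtp <- function(p) ifelse(is.na(p), "-",
                             ifelse(p < 0.001, "<.001", sprintf("%.3f", p)))
  if ("before_median" %in% names(t)) {
    out <- data.frame(
      metric = t$metric,
      before = fmt1(t$before_median, t$before_q1, t$before_q3, t$metric),
      after = fmt1(t$after_median, t$after_q1, t$after_q3, t$metric),
      n = t$n_pairs, p = fmtp(t$p_value), tier = t$tier,
      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      metric = t$metric, window = t$window,
      value = fmt1(t$median, t$q1, t$q3, t$metric),
      n = t$n, p = fmtp(t$p_value), tier = t$tier,
      stringsAsFactors = FALSE)
  }
  out
}
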