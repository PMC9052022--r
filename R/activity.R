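# Daily-summary validation and event-anchored activity windows.

#' Flag valid wear days in a daily activity table
#'
#' A day is a valid wear day when its step count reaches the threshold
#' (default 1000; the comparison is `steps >= threshold`, i.e. days with
#' *less than* 1000 steps are missing data). Invalid days contribute to no
#' window for any metric. Duplicate (participant, date) rows are rejected.
#'
#' @param daily data.frame with `participant_id`, `date` (Date or ISO
#'   character) and the metric columns of [activity_metrics].
#' @param step_threshold Minimum steps for a valid wear day (default 1000).
#' @return data.table with a logical `valid` column.
#' @export
validate_days <- function(daily, step_threshold = 1000) {
  req <- c("participant_id", "date", activity_metrics)
  missing_cols <- setdiff(req, names(daily))
  if (length(missing_cols)) {
    stop("daily table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- as.data.table(daily)
  d[, `:=`(participant_id = as.character(participant_id),
           date = as.Date(date))]
  dup <- d[, .N, by = .(participant_id, date)][N > 1L]
  if (nrow(dup)) {
    stop("duplicate (participant, date) daily records, e.g. ",
         paste(sprintf("%s/%s", head(dup$participant_id, 3L),
                       head(dup$date, 3L)), collapse = ", "),
         call. = FALSE)
  }
  d[, valid := !is.na(steps) & steps >= step_threshold]
  d[]
}

# Vectorised window statistics for many anchors at once.
# anchors: data.table with key columns + anchor_date; offsets: integer vector.
# Returns anchors + n_valid_days + one mean column per metric (NA when
# n_valid_days < min_valid_days).
.window_stats <- function(daily, anchors, offsets, min_valid_days,
                          metrics = activity_metrics) {
  stopifnot("valid" %in% names(daily))
  a <- copy(anchors)
  a[, .anchor_row := .I]
  win <- a[rep(seq_len(nrow(a)), each = length(offsets))]
  win[, date := anchor_date + rep(as.integer(offsets), times = nrow(a))]
  dv <- daily[valid == TRUE, c("participant_id", "date", metrics), with = FALSE]
  hit <- dv[win[, .(.anchor_row, participant_id, date)],
            on = c("participant_id", "date"), nomatch = NULL]
  agg <- hit[, c(.(n_valid_days = .N), lapply(.SD, mean)),
             by = .anchor_row, .SDcols = metrics]
  out <- agg[a, on = ".anchor_row"]
  out[is.na(n_valid_days), n_valid_days := 0L]
  out[n_valid_days < min_valid_days,
      (metrics) := lapply(.SD, function(x) rep(NA_real_, .N)),
      .SDcols = metrics]
  out[, .anchor_row := NULL]
  setcolorder(out, c(setdiff(names(anchors), metrics), "n_valid_days"))
  out[]
}

#' Mean activity over a dated window
#'
#' Per-metric mean over the valid wear days falling in `anchor_date +
#' day_offsets` for one participant. When fewer than `min_valid_days` valid
#' days fall in the window the means are undefined (`NA`); the valid-day
#' count is always reported.
#'
#' @param daily Validated daily table ([validate_days()]).
#' @param participant_id Participant whose window is summarised.
#' @param anchor_date Date the window is anchored at (e.g. a visit date).
#' @param day_offsets Integer day offsets relative to the anchor, e.g.
#'   `-7:-1` for the before-window.
#' @param min_valid_days Minimum valid days for defined means (default 4).
#' @param metrics Metric columns to average.
#' @return List with `metric_means` (named numeric, `NA` when undefined) and
#'   `n_valid_days`.
#' @export
window_mean <- function(daily, participant_id, anchor_date, day_offsets,
                        min_valid_days = 4, metrics = activity_metrics) {
  anchors <- data.table(participant_id = as.character(participant_id),
                        anchor_date = as.Date(anchor_date))
  res <- .window_stats(daily, anchors, day_offsets, min_valid_days, metrics)
  list(
    metric_means = setNames(as.numeric(res[1, metrics, with = FALSE]), metrics),
    n_valid_days = res$n_valid_days[1]
  )
}

.before_offsets <- -7:-1
.after_offsets <- 1:7

.week_offsets <- function(k) (7L * (k - 1L) + 1L):(7L * k)

# anchor table for a set of visits
.visit_anchors <- function(visits, tz) {
  v <- as.data.table(visits)
  v[, .(participant_id, module_id, visit_index,
        anchor_date = as.Date(start, tz = tz))]
}

#' Paired before/after observations around module visits
#'
#' For each visit, activity metrics are averaged over the 7 days prior to the
#' visit (days -7..-1) and the 7 days after it (days +1..+7); the visit day
#' itself belongs to neither window. A pair is emitted only when both windows
#' are defined (each has at least `min_valid_days` valid wear days).
#'
#' @param visits Classified visit table ([classify_completion()]).
#' @param daily Validated daily table ([validate_days()]).
#' @param completed_only If `TRUE`, only complete visits anchor pairs.
#' @param min_valid_days Minimum valid days per window (default 4).
#' @param metrics Metric columns to pair.
#' @param tz Timezone for visit-date conversion.
#' @return Long data.table: `participant_id`, `module_id`, `visit_index`,
#'   `anchor_date`, `metric`, `before`, `after`. Attributes:
#'   `n_visits_considered` (after the completion filter) and `n_pairs`
#'   (visits with both windows defined).
#' @export
build_before_after <- function(visits, daily, completed_only = FALSE,
                               min_valid_days = 4, metrics = activity_metrics,
                               tz = "UTC") {
  v <- as.data.table(visits)
  if (completed_only) {
    stopifnot("complete" %in% names(v))
    v <- v[complete == TRUE]
  }
  anchors <- .visit_anchors(v, tz)
  keys <- c("participant_id", "module_id", "visit_index", "anchor_date")
  if (nrow(anchors) == 0L) {
    out <- data.table(participant_id = character(), module_id = character(),
                      visit_index = integer(),
                      anchor_date = as.Date(character()),
                      metric = character(), before = numeric(),
                      after = numeric())
    setattr(out, "n_visits_considered", 0L)
    setattr(out, "n_pairs", 0L)
    return(out)
  }
  bef <- .window_stats(daily, anchors, .before_offsets, min_valid_days, metrics)
  aft <- .window_stats(daily, anchors, .after_offsets, min_valid_days, metrics)
  ok <- bef$n_valid_days >= min_valid_days & aft$n_valid_days >= min_valid_days
  bl <- melt(bef[ok], id.vars = c(keys, "n_valid_days"),
             measure.vars = metrics, variable.name = "metric",
             value.name = "before", variable.factor = FALSE)
  al <- melt(aft[ok], id.vars = c(keys, "n_valid_days"),
             measure.vars = metrics, variable.name = "metric",
             value.name = "after", variable.factor = FALSE)
  out <- bl[, c(keys, "metric", "before"), with = FALSE]
  out[, after := al$after]
  setattr(out, "n_visits_considered", nrow(anchors))
  setattr(out, "n_pairs", sum(ok))
  out[]
}

#' Weekly post-visit windows for the sustained-effect analysis
#'
#' For each (complete) visit, builds the before-window (days -7..-1) and the
#' eight weekly windows after the visit: week k covers days
#' `7(k-1)+1 .. 7k`, so week 1 coincides with the immediate after-window. The
#' same minimum-valid-days rule applies to every window.
#'
#' @param visits Classified visit table; only rows with `complete == TRUE`
#'   are used (others are dropped with a warning).
#' @param daily Validated daily table.
#' @param weeks Integer vector of post-visit weeks (default `1:8`).
#' @param min_valid_days Minimum valid days per window (default 4).
#' @param metrics Metric columns (default the active-minute categories).
#' @param tz Timezone for visit-date conversion.
#' @return data.table with one row per visit and window:
#'   `participant_id`, `module_id`, `visit_index`, `anchor_date`,
#'   `window_label` (`"before"`, `"week1"`, ...), `n_valid_days`, and one
#'   mean column per metric (`NA` when the window is undefined).
#' @export
weekly_windows <- function(visits, daily, weeks = 1:8, min_valid_days = 4,
                           metrics = active_minute_metrics, tz = "UTC") {
  v <- as.data.table(visits)
  if ("complete" %in% names(v) && any(!v$complete)) {
    warning("dropping ", sum(!v$complete),
            " incomplete visit(s); the sustained analysis considers only ",
            "complete module visits", call. = FALSE)
    v <- v[complete == TRUE]
  }
  anchors <- .visit_anchors(v, tz)
  windows <- c(list(before = .before_offsets),
               setNames(lapply(weeks, .week_offsets), paste0("week", weeks)))
  out <- rbindlist(lapply(names(windows), function(lbl) {
    w <- .window_stats(daily, anchors, windows[[lbl]], min_valid_days, metrics)
    w[, window_label := lbl]
    w
  }))
  setcolorder(out, c("participant_id", "module_id", "visit_index",
                     "anchor_date", "window_label", "n_valid_days"))
  setorder(out, participant_id, module_id, visit_index)
  out[]
}
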