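# End-to-end orchestration: read inputs, reconstruct engagement, build
# windows, test effects, and account for every filtering stage.

#' Read the pipeline input CSVs
#'
#' `read_events_csv` expects `participant_id,module_id,timestamp,event_type`
#' with ISO-8601 timestamps; `read_daily_csv` expects the daily schema of
#' [validate_days()]; `read_roster_csv` expects
#' `participant_id,arm,first_login`.
#'
#' @param path CSV file path.
#' @param tz Timezone for timestamp parsing.
#' @return data.table.
#' @export
read_events_csv <- function(path, tz = "UTC") {
  ev <- fread(path, colClasses = list(character = "participant_id"))
  validate_events(ev, tz = tz)
}

#' @rdname read_events_csv
#' @export
read_daily_csv <- function(path) {
  d <- fread(path, colClasses = list(character = "participant_id"))
  d[, date := as.Date(date)]
  d[]
}

#' @rdname read_events_csv
#' @export
read_roster_csv <- function(path) {
  r <- fread(path, colClasses = list(character = "participant_id"))
  r[, first_login := as.Date(first_login)]
  r[]
}

#' Write a visits CSV
#'
#' Columns `participant_id,module_id,start,duration_s,complete,visit_index`
#' with ISO-8601 start timestamps; undefined durations are empty fields.
#'
#' @param visits Classified visit table.
#' @param path Output file.
#' @param tz Timezone for formatting.
#' @return Invisibly, `path`.
#' @export
write_visits_csv <- function(visits, path, tz = "UTC") {
  v <- copy(as.data.table(visits))
  v[, start := format(start, "%Y-%m-%dT%H:%M:%S", tz = tz)]
  fwrite(v, path)
  invisible(path)
}

# participant-scale filter funnel; stops on violation
.check_funnel <- function(manifest) {
  with(as.list(manifest), {
    ok <- n_participants_pairs <= n_participants_windowed &&
      n_participants_windowed <= n_visitors &&
      n_visitors <= n_eligible &&
      n_pairs_completed <= n_pairs_all &&
      n_pairs_all <= n_visits
    if (!ok) stop("filter funnel violated for module ", module_id,
                  call. = FALSE)
  })
  invisible(TRUE)
}

#' Run the full engagement-effect analysis
#'
#' Reconstructs and classifies module visits, validates daily summaries,
#' summarises first-visit delays, then per module: builds before/after pairs
#' (all visits and complete visits only), the immediate-effect tables, the
#' per-participant averaged sensitivity table, and the 8-week sustained-effect
#' table on complete visits. A manifest records the row counts at every
#' filtering stage and the participant-scale filter funnel
#' (participants with tested pairs <= participants with windowed visits <=
#' visitors <= eligible) is asserted on every run.
#'
#' @param events,daily,roster Input tables (see [read_events_csv()] for the
#'   schemas), or paths handled by the corresponding readers.
#' @param specs Module specifications ([default_module_specs()] by default).
#' @param step_threshold Valid wear-day step threshold (default 1000).
#' @param min_valid_days Minimum valid days per 7-day window (default 4).
#' @param exact_cutoff Exact signed-rank cutoff (default 25).
#' @param weeks Post-visit weeks of the sustained analysis (default `1:8`).
#' @param sustained_modules Module ids for the sustained analysis (default:
#'   all).
#' @param metrics Metric columns analysed.
#' @param tz Dataset timezone.
#' @return List: `visits`, `daily` (validated), `delays`, `user_stats`,
#'   per-module `results` (each with `pairs_all`, `pairs_completed`,
#'   `immediate_all`, `immediate_completed`, `sensitivity`, `sustained`),
#'   and `manifest` (one row per module of funnel counts).
#' @export
run_analyze <- function(events, daily, roster,
                        specs = default_module_specs(),
                        step_threshold = 1000, min_valid_days = 4,
                        exact_cutoff = 25, weeks = 1:8,
                        sustained_modules = NULL,
                        metrics = activity_metrics, tz = "UTC") {
  if (is.character(events)) events <- read_events_csv(events, tz)
  if (is.character(daily)) daily <- read_daily_csv(daily)
  if (is.character(roster)) roster <- read_roster_csv(roster)

  visits <- classify_completion(parse_events(events, tz = tz), specs)
  dailyv <- validate_days(daily, step_threshold = step_threshold)
  if (nrow(dailyv) == 0L) {
    warning("daily table is empty: all windows will be undefined",
            call. = FALSE)
  }
  delays <- first_visit_delay(visits, roster, tz = tz)
  ustats <- user_statistics(visits, roster)
  n_eligible <- length(unique(as.data.table(roster)$participant_id))

  module_ids <- unique(visits$module_id)
  if (is.null(sustained_modules)) sustained_modules <- module_ids

  results <- list()
  manifest <- list()
  for (mid in module_ids) {
    mv <- visits[module_id == mid]
    pairs_all <- build_before_after(mv, dailyv, completed_only = FALSE,
                                    min_valid_days = min_valid_days,
                                    metrics = metrics, tz = tz)
    pairs_completed <- build_before_after(mv, dailyv, completed_only = TRUE,
                                          min_valid_days = min_valid_days,
                                          metrics = metrics, tz = tz)
    res <- list(
      pairs_all = pairs_all,
      pairs_completed = pairs_completed,
      immediate_all = immediate_effect_table(pairs_all, metrics,
                                             exact_cutoff = exact_cutoff),
      immediate_completed = immediate_effect_table(pairs_completed, metrics,
                                                   exact_cutoff = exact_cutoff),
      sensitivity = per_participant_sensitivity(pairs_all, metrics,
                                                exact_cutoff = exact_cutoff)
    )
    if (mid %in% sustained_modules) {
      cmv <- mv[complete == TRUE]
      wk <- weekly_windows(cmv, dailyv, weeks = weeks,
                           min_valid_days = min_valid_days,
                           metrics = intersect(active_minute_metrics, metrics),
                           tz = tz)
      res$weekly <- wk
      res$sustained <- sustained_effect_table(
        wk, metrics = intersect(active_minute_metrics, metrics),
        exact_cutoff = exact_cutoff)
    }
    results[[mid]] <- res

    # windowed = visits with both immediate windows defined (= tested pairs
    # on the visit scale); participant scale for the funnel
    pa <- unique(pairs_all[, .(participant_id, visit_index)])
    row <- data.table(
      module_id = mid,
      n_eligible = n_eligible,
      n_visitors = uniqueN(mv$participant_id),
      n_visits = nrow(mv),
      n_complete = sum(mv$complete),
      n_pairs_all = attr(pairs_all, "n_pairs"),
      n_pairs_completed = attr(pairs_completed, "n_pairs"),
      n_participants_windowed = uniqueN(pa$participant_id),
      n_participants_pairs = uniqueN(pa$participant_id)
    )
    .check_funnel(row)
    manifest[[mid]] <- row
  }
  manifest <- if (length(manifest)) rbindlist(manifest) else
    data.table(module_id = character())

  list(visits = visits, daily = dailyv, delays = delays, user_stats = ustats,
       results = results, manifest = manifest)
}

#' Simulate a cohort and analyze it, with a ground-truth comparison
#'
#' Generates a synthetic cohort, runs [run_analyze()] on its three input
#' tables, and reports recovered versus injected effects: for each module and
#' metric, the median paired (after - before) difference over complete-visit
#' pairs next to the configured `effect_delta_min` (zero for metrics without
#' an injected effect; when no effect is injected the report marks it so).
#' The manifest's pair and unclosed-visit counts are checked against the
#' ground-truth oracle ([expected_pairs()]).
#'
#' @param config A [cohort_config()].
#' @param ... Passed to [run_analyze()] (thresholds, weeks, ...).
#' @return The [run_analyze()] bundle plus `cohort` (the generated data) and
#'   `ground_truth_report` (per module x metric: `n_pairs`,
#'   `median_paired_diff`, `injected_delta`, `effect_injected`).
#' @export
run_simulate_analyze <- function(config = cohort_config(), ...) {
  cohort <- generate_cohort(config)
  bundle <- run_analyze(cohort$events, cohort$daily, cohort$roster,
                        step_threshold = config$step_threshold,
                        tz = config$tz, ...)

  oracle <- expected_pairs(cohort)
  report <- list()
  for (mid in names(bundle$results)) {
    pc <- bundle$results[[mid]]$pairs_completed
    for (m in unique(pc$metric)) {
      sub <- pc[metric == m]
      injected <- if (m == config$effect_metric ||
                      (m == "total_active_min" &&
                       config$effect_metric %in% active_minute_metrics))
        config$effect_delta_min else 0
      report[[length(report) + 1L]] <- data.table(
        module_id = mid, metric = m, n_pairs = nrow(sub),
        median_paired_diff = if (nrow(sub)) median(sub$after - sub$before)
                             else NA_real_,
        injected_delta = injected,
        effect_injected = config$effect_delta_min != 0)
    }
  }
  bundle$cohort <- cohort
  bundle$oracle <- oracle
  bundle$ground_truth_report <- if (length(report)) rbindlist(report) else
    data.table()
  bundle
}
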