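# Module-visit reconstruction from enter/leave log events, completion
# classification, and first-visit delay summaries.

#' Describe an intervention module
#'
#' A module specification carries the module's estimated completion duration
#' and the minimum fraction of it that a visit must last to count as complete.
#'
#' @param module_id Single string identifying the module (e.g. `"goal"`).
#' @param estimated_duration_min Estimated time to complete the module, in
#'   minutes; must be positive.
#' @param completion_fraction Fraction of the estimated duration a visit must
#'   reach to be classified complete; in (0, 1]. Default 0.33, the threshold
#'   set by intervention designers as the minimum exposure time.
#' @return An object of class `module_spec`.
#' @seealso [completion_threshold_s()], [classify_completion()]
#' @export
module_spec <- function(module_id, estimated_duration_min,
                        completion_fraction = 0.33) {
  stopifnot(
    is.character(module_id), length(module_id) == 1L, nzchar(module_id),
    is.numeric(estimated_duration_min), length(estimated_duration_min) == 1L,
    is.finite(estimated_duration_min), estimated_duration_min > 0,
    is.numeric(completion_fraction), length(completion_fraction) == 1L,
    completion_fraction > 0, completion_fraction <= 1
  )
  structure(
    list(
      module_id = module_id,
      estimated_duration_min = as.numeric(estimated_duration_min),
      completion_fraction = as.numeric(completion_fraction)
    ),
    class = "module_spec"
  )
}

#' Default module specifications
#'
#' The two physical-activity modules of the intervention toolkit: goal setting
#' and action planning ("goal", estimated 10 min) and barrier identification
#' and coping planning ("barriers", estimated 8 min).
#'
#' @return Named list of [module_spec()] objects.
#' @export
default_module_specs <- function() {
  list(
    goal = module_spec("goal", 10),
    barriers = module_spec("barriers", 8)
  )
}

#' Completion threshold of a module
#'
#' The minimum visit duration for completion: the completion fraction times the
#' estimated duration. Computed from the unrounded product; rounded values are
#' for display only.
#'
#' @param spec A [module_spec()].
#' @return Threshold in seconds (`completion_threshold_s`) or minutes
#'   (`completion_threshold_min`).
#' @examples
#' completion_threshold_min(module_spec("goal", 10)) # 3.3
#' @export
completion_threshold_s <- function(spec) {
  stopifnot(inherits(spec, "module_spec"))
  spec$completion_fraction * spec$estimated_duration_min * 60
}

#' @rdname completion_threshold_s
#' @export
completion_threshold_min <- function(spec) {
  completion_threshold_s(spec) / 60
}

.event_types <- c("enter", "leave")

#' Validate a raw log-event table
#'
#' Checks the four required columns, parses timestamps, and reports malformed
#' rows (missing participant/module id, unparseable timestamp, unknown event
#' type) by input row number rather than dropping them silently.
#'
#' @param events data.frame with columns `participant_id`, `module_id`,
#'   `timestamp` (POSIXct or ISO-8601 character), `event_type`
#'   (`"enter"`/`"leave"`).
#' @param tz Timezone in which character timestamps are interpreted; one
#'   declared timezone per dataset.
#' @return data.table with parsed columns plus `.row` (input row number).
#'   Malformed input raises an error of class `modact_bad_rows` whose
#'   `bad_rows` field is a table of offending rows and reasons.
#' @export
validate_events <- function(events, tz = "UTC") {
  req <- c("participant_id", "module_id", "timestamp", "event_type")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols)) {
    stop("events table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ev <- as.data.table(events)[, ..req]
  ev[, `:=`(
    participant_id = as.character(participant_id),
    module_id = as.character(module_id),
    event_type = as.character(event_type)
  )]
  ev[, .row := .I]
  ts <- ev$timestamp
  if (!inherits(ts, "POSIXct")) {
    ts <- as.character(ts)
    # element-wise parsing: unparseable rows become NA and are reported
    # below instead of aborting the whole read
    parsed <- as.POSIXct(strptime(ts, "%Y-%m-%dT%H:%M:%OS", tz = tz))
    alt <- as.POSIXct(strptime(ts, "%Y-%m-%d %H:%M:%OS", tz = tz))
    parsed[is.na(parsed)] <- alt[is.na(parsed)]
  } else {
    parsed <- ts
  }
  ev[, timestamp := parsed]

  reason <- rep(NA_character_, nrow(ev))
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(is.na(ev$participant_id) | !nzchar(ev$participant_id),
                "missing participant_id")
  reason <- bad(is.na(ev$module_id) | !nzchar(ev$module_id),
                "missing module_id")
  reason <- bad(is.na(ev$timestamp), "missing or unparseable timestamp")
  reason <- bad(!(ev$event_type %in% .event_types),
                "unknown event_type (expected enter/leave)")
  if (any(!is.na(reason))) {
    bad_rows <- data.table(row = ev$.row[!is.na(reason)],
                           reason = reason[!is.na(reason)])
    msg <- paste0(
      nrow(bad_rows), " malformed event row(s); first few: ",
      paste(sprintf("row %d (%s)", head(bad_rows$row, 5L),
                    head(bad_rows$reason, 5L)), collapse = "; ")
    )
    cond <- structure(
      class = c("modact_bad_rows", "error", "condition"),
      list(message = msg, call = sys.call(-1), bad_rows = bad_rows)
    )
    stop(cond)
  }
  ev[]
}

#' Reconstruct module visits from log events
#'
#' Each `enter` event is matched to the next `leave` for the same participant
#' and module with no intervening `enter`; matching is strictly per
#' (participant, module), so entering one module never closes an open visit of
#' another. An `enter` with no such `leave` yields a visit with undefined
#' (`NA`) duration — the end event is missing. A `leave` with no open `enter`
#' is discarded with a warning and counted in the `n_orphan_leaves` attribute.
#' Events with equal timestamps order `enter` before `leave`, so a zero-length
#' visit (enter and leave at the same instant) is kept with duration 0.
#'
#' @inheritParams validate_events
#' @return data.table of visits: `participant_id`, `module_id`, `start`
#'   (POSIXct of the enter event), `duration_s` (seconds, `NA` if the end
#'   event is missing), `visit_index` (1-based, chronological within
#'   participant and module). Attribute `n_orphan_leaves` counts discarded
#'   leave events.
#' @export
parse_events <- function(events, tz = "UTC") {
  ev <- validate_events(events, tz = tz)
  if (nrow(ev) == 0L) {
    out <- data.table(
      participant_id = character(), module_id = character(),
      start = as.POSIXct(character(), tz = tz),
      duration_s = numeric(), visit_index = integer()
    )
    setattr(out, "n_orphan_leaves", 0L)
    return(out)
  }
  # enter sorts before leave at equal timestamps
  ev[, ord := match(event_type, .event_types)]
  setorder(ev, participant_id, module_id, timestamp, ord)

  ev[, `:=`(
    next_type = shift(event_type, type = "lead"),
    next_ts = shift(timestamp, type = "lead"),
    prev_type = shift(event_type, type = "lag")
  ), by = .(participant_id, module_id)]

  orphan <- ev$event_type == "leave" &
    (is.na(ev$prev_type) | ev$prev_type != "enter")
  n_orphan <- sum(orphan)
  if (n_orphan > 0L) {
    warning(n_orphan, " leave event(s) with no open enter were discarded ",
            "(input rows ", paste(head(ev$.row[orphan], 5L), collapse = ", "),
            if (n_orphan > 5L) ", ..." else "", ")", call. = FALSE)
  }

  enters <- ev[event_type == "enter"]
  closed <- !is.na(enters$next_type) & enters$next_type == "leave"
  visits <- enters[, .(
    participant_id, module_id, start = timestamp,
    duration_s = ifelse(closed,
                        as.numeric(next_ts) - as.numeric(timestamp),
                        NA_real_)
  )]
  setorder(visits, participant_id, module_id, start)
  visits[, visit_index := seq_len(.N), by = .(participant_id, module_id)]
  setattr(visits, "n_orphan_leaves", as.integer(n_orphan))
  visits[]
}

#' Classify visit completion
#'
#' A visit is complete if it lasted at least the completion fraction of the
#' module's estimated duration (inclusive comparison — "at least"), or if its
#' duration could not be determined because the end event is missing.
#'
#' @param visits Visit table from [parse_events()].
#' @param specs A [module_spec()] or list of them covering every `module_id`
#'   present in `visits`.
#' @return `visits` with a logical `complete` column added.
#' @export
classify_completion <- function(visits, specs = default_module_specs()) {
  if (inherits(specs, "module_spec")) specs <- list(specs)
  v <- as.data.table(visits)
  thr <- data.table(
    module_id = vapply(specs, `[[`, "", "module_id"),
    threshold_s = vapply(specs, completion_threshold_s, 0)
  )
  unknown <- setdiff(unique(v$module_id), thr$module_id)
  if (length(unknown)) {
    stop("no module_spec for module(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(v$duration_s) & v$duration_s < 0)) {
    stop("negative visit duration encountered; this indicates a parser bug",
         call. = FALSE)
  }
  v <- thr[v, on = "module_id"]
  # tolerance absorbs float error in fraction * minutes * 60 (e.g. 198 s for
  # the 10-min module is "at least 33%" even though 0.33*600 > 198 in doubles)
  v[, complete := is.na(duration_s) | duration_s >= threshold_s - 1e-9]
  v[, threshold_s := NULL]
  setcolorder(v, c("participant_id", "module_id", "start", "duration_s",
                   "complete", "visit_index"))
  setorder(v, participant_id, module_id, start)
  v[]
}

#' Days from first login to first module visit
#'
#' For each participant and module, the whole-day delay between the
#' participant's first login and the date of their earliest visit, summarised
#' per module as median and quartiles. Visits dated before the first login are
#' flagged as data errors and excluded with a warning.
#'
#' @param visits Visit table from [parse_events()] (completion not required).
#' @param roster data.frame with `participant_id` and `first_login` (Date or
#'   ISO character).
#' @param tz Timezone used to convert visit start instants to calendar dates.
#' @param quantile_type Quartile convention passed to [stats::quantile()]
#'   (default type 7, linear interpolation).
#' @return List with `delays` (per participant-module delay in days) and
#'   `summary` (per module: `n`, `median_days`, `q1_days`, `q3_days`; a module
#'   with no valid delays yields `n = 0` and `NA` summaries).
#' @export
first_visit_delay <- function(visits, roster, tz = "UTC", quantile_type = 7) {
  v <- as.data.table(visits)
  r <- as.data.table(roster)[, .(participant_id = as.character(participant_id),
                                 first_login = as.Date(first_login))]
  modules <- unique(v$module_id)
  if (nrow(v) == 0L) {
    return(list(
      delays = data.table(participant_id = character(),
                          module_id = character(), delay_days = integer()),
      summary = data.table(module_id = character(), n = integer(),
                           median_days = numeric(), q1_days = numeric(),
                           q3_days = numeric())
    ))
  }
  missing_ids <- setdiff(unique(v$participant_id), r$participant_id)
  if (length(missing_ids)) {
    stop("participants absent from roster: ",
         paste(head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  }
  firsts <- v[, .(first_start = min(start)), by = .(participant_id, module_id)]
  firsts <- r[firsts, on = "participant_id"]
  firsts[, delay_days := as.integer(as.Date(first_start, tz = tz) - first_login)]
  neg <- firsts$delay_days < 0
  if (any(neg)) {
    warning(sum(neg), " first visit(s) dated before first login were ",
            "excluded as data errors", call. = FALSE)
    firsts <- firsts[!neg]
  }
  summ <- firsts[, {
    q <- quantile(delay_days, c(0.25, 0.5, 0.75), type = quantile_type,
                  names = FALSE)
    .(n = .N, median_days = q[2], q1_days = q[1], q3_days = q[3])
  }, by = module_id]
  # modules whose visits were all excluded: undefined, not zero
  gone <- setdiff(modules, summ$module_id)
  if (length(gone)) {
    summ <- rbind(summ, data.table(module_id = gone, n = 0L,
                                   median_days = NA_real_, q1_days = NA_real_,
                                   q3_days = NA_real_))
  }
  list(delays = firsts[, .(participant_id, module_id, delay_days)],
       summary = summ[])
}

#' Per-module user-statistics funnel
#'
#' Counts eligible participants, module visitors (with percentage of
#' eligible), visits and complete visits — the engagement accounting that
#' precedes the effect analyses.
#'
#' @param visits Classified visit table ([classify_completion()]).
#' @param roster Participant roster (one row per eligible participant).
#' @return data.table, one row per module.
#' @export
user_statistics <- function(visits, roster) {
  v <- as.data.table(visits)
  n_eligible <- length(unique(as.data.table(roster)$participant_id))
  out <- v[, .(
    n_eligible = n_eligible,
    n_visitors = uniqueN(participant_id),
    n_visits = .N,
    n_complete = sum(complete)
  ), by = module_id]
  out[, pct_visitors := percentage(n_visitors, n_eligible)]
  out[]
}
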