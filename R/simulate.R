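# Seeded synthetic-cohort generator: log events, daily tracker summaries,
# roster, and the ground truth needed to verify every pipeline stage.

#' Simulation parameters for one module
#'
#' Visit behaviour for one intervention module: whether and when participants
#' first visit, how often they return, and how visit durations fall relative
#' to the completion threshold.
#'
#' @param module_id,estimated_duration_min,completion_fraction As
#'   [module_spec()].
#' @param visit_prob Probability an eligible participant ever visits.
#' @param delay_meanlog,delay_sdlog Lognormal parameters of the first-visit
#'   delay (days after first login); `exp(delay_meanlog)` is the median delay.
#' @param p_complete Probability a visit's duration exceeds the completion
#'   threshold (visits with a missing end event are complete regardless).
#' @param revisit_rate Poisson mean of extra visits per visitor.
#' @param revisit_gap_mean_days Mean gap (days) between successive visits.
#' @return List of class `sim_module`.
#' @export
sim_module <- function(module_id, estimated_duration_min, visit_prob,
                       delay_meanlog, delay_sdlog, p_complete,
                       revisit_rate = 0.26, revisit_gap_mean_days = 21,
                       completion_fraction = 0.33) {
  stopifnot(visit_prob >= 0, visit_prob <= 1,
            p_complete >= 0, p_complete <= 1,
            delay_sdlog > 0, revisit_rate >= 0, revisit_gap_mean_days > 0)
  structure(list(
    module_id = module_id,
    estimated_duration_min = estimated_duration_min,
    completion_fraction = completion_fraction,
    visit_prob = visit_prob,
    delay_meanlog = delay_meanlog, delay_sdlog = delay_sdlog,
    p_complete = p_complete,
    revisit_rate = revisit_rate,
    revisit_gap_mean_days = revisit_gap_mean_days
  ), class = "sim_module")
}

#' Default simulated modules
#'
#' Goal-like module: 10 min estimated duration, 61.4% visit probability,
#' first-visit delay lognormal with median 55 days; about half of timed
#' visits exceed the threshold. Barriers-like module: 8 min, 50.1%, median
#' delay 98 days, about two thirds complete. Extra visits per visitor are
#' Poisson(~0.26), giving roughly 1.26 visits per visitor.
#'
#' @return Named list of [sim_module()] objects.
#' @export
default_sim_modules <- function() {
  list(
    goal = sim_module("goal", 10, visit_prob = 0.614,
                      delay_meanlog = log(55), delay_sdlog = 0.21,
                      p_complete = 0.49, revisit_rate = 0.26),
    barriers = sim_module("barriers", 8, visit_prob = 0.501,
                          delay_meanlog = log(98), delay_sdlog = 0.14,
                          p_complete = 0.67, revisit_rate = 0.27)
  )
}

#' Cohort simulation configuration
#'
#' All parameters of the synthetic cohort. Defaults emulate the trial-like
#' setting the pipeline targets: ~800 eligible participants in two
#' intervention arms, lognormal daily steps with median ~9500, gamma-like
#' active minutes with medians near 17 (fairly) and 24 (very) min, 90% wear
#' days (non-wear days get fewer than 1000 steps), and an optional additive
#' post-completion effect on an active-minute metric that can decay linearly
#' over a configured number of weeks.
#'
#' @param n_participants Number of eligible participants.
#' @param modules List of [sim_module()]s.
#' @param p_missing_end Probability a visit's leave event is dropped from the
#'   log (such visits classify complete by the missing-end rule).
#' @param baseline_steps List: `meanlog` (log median daily steps),
#'   `sdlog_between` (between-person), `sdlog_day` (day-to-day).
#' @param baseline_active List: `fairly_mean`, `very_mean` (population mean
#'   daily minutes), `sdlog_between` (between-person lognormal spread of the
#'   personal mean), `shape_day` (gamma shape of day-to-day variation; the
#'   day-level coefficient of variation is `1/sqrt(shape_day)`).
#' @param wear_prob Probability a participant-day is a wear day.
#' @param nonwear_drop_rows If `TRUE`, non-wear days are omitted from the
#'   daily table (absent dates); if `FALSE` (default) they are emitted with
#'   steps drawn uniformly in \[0, 999\], exercising the threshold filter.
#' @param effect_delta_min Additive change (minutes) applied to
#'   `effect_metric` on wear days from day +1 after a participant's most
#'   recent completed visit.
#' @param effect_decay_weeks If 0, the effect persists undiminished;
#'   otherwise it decays linearly from full size on day +1 to zero after
#'   `7 * effect_decay_weeks` days.
#' @param effect_metric Which active-minute metric receives the effect
#'   (`total_active_min` is always fairly + very by construction, so it
#'   inherits the effect).
#' @param n_days Days of daily data generated per participant, from first
#'   login.
#' @param start_date First possible login date.
#' @param login_stagger_days First logins are uniform over this many days
#'   from `start_date`.
#' @param step_threshold Wear-day step threshold used by the oracle.
#' @param seed Integer seed; identical config and seed give identical output.
#' @param tz Timezone stamped on event timestamps.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 800,
                          modules = default_sim_modules(),
                          p_missing_end = 0.1,
                          baseline_steps = list(meanlog = log(9500),
                                                sdlog_between = 0.30,
                                                sdlog_day = 0.25),
                          baseline_active = list(fairly_mean = 18,
                                                 very_mean = 26,
                                                 sdlog_between = 0.45,
                                                 shape_day = 4),
                          wear_prob = 0.9,
                          nonwear_drop_rows = FALSE,
                          effect_delta_min = 0,
                          effect_decay_weeks = 0,
                          effect_metric = "very_active_min",
                          n_days = 250,
                          start_date = as.Date("2017-06-01"),
                          login_stagger_days = 60,
                          step_threshold = 1000,
                          seed = 1,
                          tz = "UTC") {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(n_participants) && n_participants >= 0 &&
        n_participants == floor(n_participants),
      "n_participants: must be a nonnegative integer")
  chk(length(modules) >= 1 && all(vapply(modules, inherits, TRUE, "sim_module")),
      "modules: must be a nonempty list of sim_module objects")
  chk(p_missing_end >= 0 && p_missing_end <= 1,
      "p_missing_end: must be in [0, 1]")
  chk(wear_prob >= 0 && wear_prob <= 1, "wear_prob: must be in [0, 1]")
  chk(baseline_steps$sdlog_between > 0 && baseline_steps$sdlog_day > 0,
      "baseline_steps: scales must be positive")
  chk(baseline_active$fairly_mean > 0 && baseline_active$very_mean > 0 &&
        baseline_active$sdlog_between > 0 && baseline_active$shape_day > 0,
      "baseline_active: all parameters must be positive")
  chk(effect_decay_weeks >= 0, "effect_decay_weeks: must be >= 0")
  chk(effect_metric %in% c("fairly_active_min", "very_active_min"),
      "effect_metric: must be fairly_active_min or very_active_min")
  chk(n_days >= 1, "n_days: must be >= 1")
  chk(step_threshold > 0, "step_threshold: must be positive")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
      "seed: must be a single finite number")
  if (length(problems)) {
    stop("invalid cohort_config:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  structure(as.list(environment())[c(
    "n_participants", "modules", "p_missing_end", "baseline_steps",
    "baseline_active", "wear_prob", "nonwear_drop_rows", "effect_delta_min",
    "effect_decay_weeks", "effect_metric", "n_days", "start_date",
    "login_stagger_days", "step_threshold", "seed", "tz"
  )], class = "cohort_config")
}

.empty_cohort <- function(config) {
  list(
    events = data.table(participant_id = character(), module_id = character(),
                        timestamp = as.POSIXct(character(), tz = config$tz),
                        event_type = character()),
    daily = data.table(participant_id = character(),
                       date = as.Date(character()), steps = integer(),
                       energy_kcal = numeric(), fairly_active_min = numeric(),
                       very_active_min = numeric(),
                       total_active_min = numeric(), distance_km = numeric()),
    roster = data.table(participant_id = character(), arm = character(),
                        first_login = as.Date(character())),
    ground_truth = list(
      visits = data.table(participant_id = character(),
                          module_id = character(),
                          start = as.POSIXct(character(), tz = config$tz),
                          visit_date = as.Date(character()),
                          duration_s = numeric(), missing_end = logical(),
                          true_complete = logical(), visit_index = integer()),
      daily = data.table(participant_id = character(),
                         date = as.Date(character()), wear = logical(),
                         steps = integer(), baseline_fairly = numeric(),
                         baseline_very = numeric(), effect_min = numeric())
    ),
    config = config
  )
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws, per participant: a first-login date, per-module visit occurrence,
#' first-visit delay (lognormal), optional repeat visits, and visit durations
#' placed above or below the completion threshold per the module's
#' `p_complete` (with `p_missing_end` of visits losing their leave event);
#' and per participant-day: wear status, lognormal steps, gamma active
#' minutes, distance and energy co-varying with steps. After a participant's
#' most recent completed visit, the configured effect is added to the effect
#' metric on wear days (from day +1, decaying if configured);
#' `total_active_min` is always `fairly + very`.
#'
#' @param config A [cohort_config()].
#' @return List with `events`, `daily`, `roster` (the three pipeline input
#'   tables), `ground_truth` (`$visits` with true completion flags and
#'   durations including those hidden by missing end events; `$daily` with
#'   wear flags, pre-effect baselines and the exact per-day effect
#'   contribution) and the echoed `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_participants)
  if (n == 0L) return(.empty_cohort(config))

  pid <- sprintf("p%04d", seq_len(n))
  first_login <- config$start_date +
    (sample.int(config$login_stagger_days + 1L, n, replace = TRUE) - 1L)
  arm <- sample(c("motivation", "combined"), n, replace = TRUE)
  roster <- data.table(participant_id = pid, arm = arm,
                       first_login = first_login)

  bs <- config$baseline_steps
  ba <- config$baseline_active
  steps_meanlog_i <- rnorm(n, bs$meanlog, bs$sdlog_between)
  fairly_mean_i <- ba$fairly_mean * rlnorm(n, 0, ba$sdlog_between)
  very_mean_i <- ba$very_mean * rlnorm(n, 0, ba$sdlog_between)
  stride_km_i <- rnorm(n, 7.1e-4, 5e-5) # km per step
  energy_base_i <- rnorm(n, 500, 80)
  energy_per_step_i <- rnorm(n, 0.075, 0.008)

  # ---- daily grid ----
  grid <- CJ(pidx = seq_len(n), day = 0:(config$n_days - 1L))
  nd <- nrow(grid)
  wear <- runif(nd) < config$wear_prob
  steps_wear <- rlnorm(nd, steps_meanlog_i[grid$pidx], bs$sdlog_day)
  steps_nonwear <- floor(runif(nd, 0, config$step_threshold))
  steps <- as.integer(round(ifelse(wear, steps_wear, steps_nonwear)))
  shape <- ba$shape_day
  fairly_wear <- rgamma(nd, shape = shape,
                        rate = shape / fairly_mean_i[grid$pidx])
  very_wear <- rgamma(nd, shape = shape, rate = shape / very_mean_i[grid$pidx])
  fairly <- ifelse(wear, fairly_wear, runif(nd, 0, 5))
  very <- ifelse(wear, very_wear, runif(nd, 0, 3))
  daily <- data.table(
    pidx = grid$pidx,
    participant_id = pid[grid$pidx],
    date = first_login[grid$pidx] + grid$day,
    wear = wear, steps = steps,
    baseline_fairly = fairly, baseline_very = very
  )

  # ---- visits ----
  visit_list <- list()
  for (m in config$modules) {
    visited <- which(runif(n) < m$visit_prob)
    nv1 <- length(visited)
    if (nv1 == 0L) next
    first_delay <- pmax(1, round(rlnorm(nv1, m$delay_meanlog, m$delay_sdlog)))
    n_extra <- rpois(nv1, m$revisit_rate)
    vt <- data.table(pidx = rep(visited, n_extra + 1L),
                     is_first = unlist(lapply(n_extra + 1L,
                                              function(k) c(TRUE, rep(FALSE, k - 1L)))))
    gaps <- pmax(1, round(rexp(nrow(vt), 1 / m$revisit_gap_mean_days)))
    vt[, gap := ifelse(is_first, 0, gaps)]
    vt[, day_off := cumsum(gap), by = pidx]
    vt[, visit_day := rep(first_delay, n_extra + 1L) + day_off]
    nv <- nrow(vt)
    tod_s <- floor(runif(nv, 8 * 3600, 20 * 3600))
    thr_s <- completion_threshold_s(
      module_spec(m$module_id, m$estimated_duration_min, m$completion_fraction))
    over <- runif(nv) < m$p_complete
    dur <- ifelse(over, thr_s * runif(nv, 1, 3), runif(nv, 10, thr_s - 1))
    missing_end <- runif(nv) < config$p_missing_end
    vt[, `:=`(
      module_id = m$module_id,
      visit_date = first_login[pidx] + visit_day,
      start = as.POSIXct(as.character(first_login[pidx] + visit_day),
                         tz = config$tz) + tod_s,
      duration_s = round(dur), # log events have whole-second resolution
      missing_end = missing_end
    )]
    vt[, true_complete := missing_end | duration_s >= thr_s - 1e-9]
    visit_list[[m$module_id]] <- vt
  }
  if (length(visit_list)) {
    gt_visits <- rbindlist(visit_list)[, .(
      participant_id = pid[pidx], pidx, module_id, start, visit_date,
      duration_s, missing_end, true_complete)]
    setorder(gt_visits, participant_id, module_id, start)
    gt_visits[, visit_index := seq_len(.N), by = .(participant_id, module_id)]
  } else {
    gt_visits <- .empty_cohort(config)$ground_truth$visits
    gt_visits[, pidx := integer()]
  }

  # ---- effect injection: most recent completed visit drives the effect ----
  effect <- numeric(nrow(daily))
  if (config$effect_delta_min != 0 && nrow(gt_visits) > 0L) {
    cv <- gt_visits[true_complete == TRUE, .(participant_id, vdate = visit_date)]
    if (nrow(cv)) {
      setkey(cv, participant_id, vdate)
      look <- daily[, .(participant_id, jdate = date - 1L)]
      # most recent completed-visit date <= day - 1 (x.vdate keeps cv's value)
      # mult = "last": two completed visits on one date share the offset
      hit <- cv[look, .(matched_vdate = x.vdate),
                on = .(participant_id, vdate = jdate), roll = +Inf,
                mult = "last"]
      offset <- as.numeric(daily$date - hit$matched_vdate)
      mult <- ifelse(is.na(offset), 0,
                     if (config$effect_decay_weeks == 0) 1 else
                       pmax(0, 1 - (offset - 1) / (7 * config$effect_decay_weeks)))
      effect <- config$effect_delta_min * mult * as.numeric(daily$wear)
    }
  }
  daily[, effect_min := effect]

  fairly_out <- daily$baseline_fairly +
    if (config$effect_metric == "fairly_active_min") daily$effect_min else 0
  very_out <- daily$baseline_very +
    if (config$effect_metric == "very_active_min") daily$effect_min else 0
  daily_out <- data.table(
    participant_id = daily$participant_id,
    date = daily$date,
    steps = daily$steps,
    energy_kcal = round(energy_base_i[daily$pidx] +
                          energy_per_step_i[daily$pidx] * daily$steps, 1),
    fairly_active_min = fairly_out,
    very_active_min = very_out,
    total_active_min = fairly_out + very_out,
    distance_km = round(stride_km_i[daily$pidx] * daily$steps, 2)
  )
  if (config$nonwear_drop_rows) daily_out <- daily_out[daily$wear]

  # ---- events ----
  if (nrow(gt_visits)) {
    enter <- gt_visits[, .(participant_id, module_id, timestamp = start,
                           event_type = "enter")]
    leave <- gt_visits[missing_end == FALSE,
                       .(participant_id, module_id,
                         timestamp = start + duration_s,
                         event_type = "leave")]
    events <- rbind(enter, leave)
    setorder(events, participant_id, timestamp, event_type)
  } else {
    events <- .empty_cohort(config)$events
  }

  gt_daily <- daily[, .(participant_id, date, wear, steps,
                        baseline_fairly, baseline_very, effect_min)]
  gt_visits[, pidx := NULL]

  list(events = events[], daily = daily_out[], roster = roster[],
       ground_truth = list(visits = gt_visits[], daily = gt_daily[]),
       config = config)
}

#' Ground-truth oracle for pairing and filtering
#'
#' Recomputes, from the ground truth alone and with plain loops independent
#' of the pipeline's join logic, which visits yield a valid before/after
#' pair: a day is valid iff a daily row exists (not dropped) with
#' `steps >= step_threshold`, and each 7-day window needs at least
#' `min_valid_days` of them. Used only to verify the pipeline.
#'
#' @param cohort Output of [generate_cohort()].
#' @param min_valid_days Minimum valid days per window (default 4).
#' @return List: `per_visit` (each ground-truth visit with
#'   `n_before_valid`, `n_after_valid`, `has_pair`), `n_pairs`,
#'   `n_pairs_completed`, `n_unclosed` (visits whose leave event is
#'   missing), `n_valid_days` (total valid participant-days).
#' @export
expected_pairs <- function(cohort, min_valid_days = 4) {
  cfg <- cohort$config
  gd <- cohort$ground_truth$daily
  if (cfg$nonwear_drop_rows) gd <- gd[wear == TRUE]
  valid_key <- paste(gd$participant_id[gd$steps >= cfg$step_threshold],
                     gd$date[gd$steps >= cfg$step_threshold])
  gv <- cohort$ground_truth$visits
  n_before <- integer(nrow(gv))
  n_after <- integer(nrow(gv))
  if (nrow(gv)) {
    for (i in seq_len(nrow(gv))) {
      p <- gv$participant_id[i]
      d <- gv$visit_date[i]
      n_before[i] <- sum(paste(p, d - 7:1) %in% valid_key)
      n_after[i] <- sum(paste(p, d + 1:7) %in% valid_key)
    }
  }
  per_visit <- copy(gv)
  per_visit[, `:=`(n_before_valid = n_before, n_after_valid = n_after,
                   has_pair = n_before >= min_valid_days &
                     n_after >= min_valid_days)]
  list(per_visit = per_visit[],
       n_pairs = sum(per_visit$has_pair),
       n_pairs_completed = sum(per_visit$has_pair & per_visit$true_complete),
       n_unclosed = sum(per_visit$missing_end),
       n_valid_days = length(valid_key))
}

#' Single-module experiment configuration
#'
#' The cohort design used by the pipeline's calibration and power
#' experiments (type-I error, effect recovery, sustained-effect shape): only
#' the barriers-like module is simulated and every visitor makes exactly one
#' visit (revisit rate 0), so a visit's windows are never contaminated by the
#' effect of another exposure and the median paired difference estimates the
#' injected delta directly. `n_days` defaults to the visit-delay distribution
#' plus the analysis horizon.
#'
#' @param n_participants Cohort size.
#' @param effect_delta_min Injected effect (minutes) on very-active minutes.
#' @param effect_decay_weeks Linear decay horizon (0 = persistent).
#' @param seed Seed.
#' @param n_days Days of daily data; default covers the delay spread plus
#'   `horizon_weeks` of follow-up.
#' @param horizon_weeks Follow-up weeks the daily data must cover.
#' @return A [cohort_config()].
#' @export
experiment_config <- function(n_participants, effect_delta_min = 0,
                              effect_decay_weeks = 0, seed = 1,
                              horizon_weeks = 1,
                              n_days = 160 + 7 * horizon_weeks) {
  m <- default_sim_modules()$barriers
  m$revisit_rate <- 0
  cohort_config(
    n_participants = n_participants,
    modules = list(barriers = m),
    effect_delta_min = effect_delta_min,
    effect_decay_weeks = effect_decay_weeks,
    effect_metric = "very_active_min",
    n_days = n_days,
    seed = seed
  )
}

#' Write the cohort's CSV files
#'
#' Emits the three pipeline input CSVs (`events.csv`, `daily.csv`,
#' `roster.csv`) and the ground-truth tables (`ground_truth_visits.csv`,
#' `ground_truth_daily.csv`) with ISO dates/timestamps; undefined durations
#' are empty fields.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- copy(cohort$events)
  ev[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%S",
                           tz = cohort$config$tz)]
  gv <- copy(cohort$ground_truth$visits)
  gv[, start := format(start, "%Y-%m-%dT%H:%M:%S", tz = cohort$config$tz)]
  paths <- c(
    events = file.path(dir, "events.csv"),
    daily = file.path(dir, "daily.csv"),
    roster = file.path(dir, "roster.csv"),
    gt_visits = file.path(dir, "ground_truth_visits.csv"),
    gt_daily = file.path(dir, "ground_truth_daily.csv")
  )
  fwrite(ev, paths["events"])
  fwrite(cohort$daily, paths["daily"])
  fwrite(cohort$roster, paths["roster"])
  fwrite(gv, paths["gt_visits"])
  fwrite(cohort$ground_truth$daily, paths["gt_daily"])
  invisible(paths)
}
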