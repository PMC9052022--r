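# In-code fixtures shared across test files.

make_events <- function(...) {
  rows <- list(...)
  empty <- data.table::data.table(participant_id = character(),
                                  module_id = character(),
                                  timestamp = character(),
                                  event_type = character())
  if (!length(rows)) return(empty)
  data.table::rbindlist(c(list(empty), lapply(rows, function(r) {
    data.table::data.table(participant_id = r[[1]], module_id = r[[2]],
                           timestamp = r[[3]], event_type = r[[4]])
  })))
}

# daily table for one participant: `values` named list metric -> vector, one
# entry per date; unspecified metrics get a constant
make_daily <- function(participant_id, dates, steps,
                       values = list(), fill = 10) {
  d <- data.table::data.table(
    participant_id = participant_id, date = as.Date(dates),
    steps = steps, energy_kcal = fill, fairly_active_min = fill,
    very_active_min = fill, total_active_min = fill, distance_km = fill
  )
  for (m in names(values)) d[[m]] <- values[[m]]
  d
}

one_visit <- function(participant_id = "p1", module_id = "barriers",
                      date = "2020-03-10", complete = TRUE) {
  data.table::data.table(
    participant_id = participant_id, module_id = module_id,
    start = as.POSIXct(paste(date, "10:00:00"), tz = "UTC"),
    duration_s = 600, complete = complete, visit_index = 1L
  )
}

small_cohort_config <- function(n = 60, seed = 42, ...) {
  cohort_config(n_participants = n, seed = seed, n_days = 170, ...)
}
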