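test_that("enter/leave streams are matched into visits with correct durations", {
  expect_equal(nrow(parse_events(make_events())), 0L)

  v <- parse_events(make_events(
    list("p1", "goal", "2020-01-01T10:00:00", "enter"),
    list("p1", "goal", "2020-01-01T10:05:00", "leave")
  ))
  expect_equal(nrow(v), 1L)
  expect_equal(v$duration_s, 300)
  expect_equal(v$visit_index, 1L)

  # an enter with no leave before the next enter stays open (missing end)
  v2 <- parse_events(make_events(
    list("p1", "goal", "2020-01-01T10:00:00", "enter"),
    list("p1", "goal", "2020-01-01T11:00:00", "enter"),
    list("p1", "goal", "2020-01-01T11:04:00", "leave")
  ))
  expect_equal(nrow(v2), 2L)
  expect_equal(v2$duration_s, c(NA_real_, 240))
  expect_equal(v2$visit_index, c(1L, 2L))
})

test_that("matching is per participant-module; other modules never close a visit", {
  v <- parse_events(make_events(
    list("p1", "goal", "2020-01-01T10:00:00", "enter"),
    list("p1", "barriers", "2020-01-01T10:02:00", "enter"),
    list("p1", "barriers", "2020-01-01T10:03:00", "leave"),
    list("p1", "goal", "2020-01-01T10:10:00", "leave"),
    list("p2", "goal", "2020-01-01T10:01:00", "enter"),
    list("p2", "goal", "2020-01-01T10:06:00", "leave")
  ))
  expect_equal(nrow(v), 3L)
  goal1 <- v[v$participant_id == "p1" & v$module_id == "goal"]
  expect_equal(goal1$duration_s, 600)
  expect_equal(v[v$module_id == "barriers"]$duration_s, 60)
})

test_that("orphan leaves are discarded with a warning and counted", {
  ev <- make_events(
    list("p1", "goal", "2020-01-01T09:00:00", "leave"),
    list("p1", "goal", "2020-01-01T10:00:00", "enter"),
    list("p1", "goal", "2020-01-01T10:05:00", "leave"),
    list("p1", "goal", "2020-01-01T10:06:00", "leave")
  )
  expect_warning(v <- parse_events(ev), "no open enter")
  expect_equal(nrow(v), 1L)
  expect_equal(v$duration_s, 300)
  expect_equal(attr(v, "n_orphan_leaves"), 2L)
})

test_that("zero-length visits are kept with duration 0 and classify incomplete", {
  v <- parse_events(make_events(
    list("p1", "goal", "2020-01-01T10:00:00", "enter"),
    list("p1", "goal", "2020-01-01T10:00:00", "leave")
  ))
  expect_equal(v$duration_s, 0)
  cv <- classify_completion(v)
  expect_false(cv$complete)
})

test_that("malformed rows are rejected with a row-level report, not dropped", {
  ev <- make_events(
    list("p1", "goal", "2020-01-01T10:00:00", "enter"),
    list("p1", "goal", "2020-01-01T10:05:00", "exit"),   # bad event_type
    list("", "goal", "2020-01-01T10:06:00", "leave"),    # missing id
    list("p1", "goal", "not-a-time", "leave")            # bad timestamp
  )
  err <- tryCatch(parse_events(ev), error = function(e) e)
  expect_s3_class(err, "modact_bad_rows")
  expect_equal(sort(err$bad_rows$row), c(2L, 3L, 4L))
  expect_match(err$message, "malformed")
  expect_error(parse_events(data.frame(participant_id = "p1")),
               "missing column")
})

test_that("completion rule: inclusive threshold, missing end counts complete", {
  goal <- module_spec("goal", 10)
  mk <- function(dur) data.table::data.table(
    participant_id = "p1", module_id = "goal",
    start = as.POSIXct("2020-01-01 10:00:00", tz = "UTC"),
    duration_s = dur, visit_index = 1L)

  expect_equal(completion_threshold_s(goal), 198)
  expect_true(classify_completion(mk(198), goal)$complete)   # 3.3 min exactly
  expect_false(classify_completion(mk(197), goal)$complete)
  expect_true(classify_completion(mk(NA_real_), goal)$complete)
  expect_error(classify_completion(mk(-1), goal), "negative")
  expect_error(classify_completion(mk(100), module_spec("other", 5)),
               "no module_spec")
})

test_that("completion is monotone in duration for a fixed module spec", {
  spec <- module_spec("barriers", 8)
  set.seed(101)
  for (i in 1:20) {
    durs <- sort(runif(40, 0, 400))
    v <- data.table::data.table(
      participant_id = "p1", module_id = "barriers",
      start = as.POSIXct("2020-01-01", tz = "UTC") + seq_along(durs) * 3600,
      duration_s = durs, visit_index = seq_along(durs))
    flags <- classify_completion(v, spec)$complete
    expect_true(all(diff(as.integer(flags)) >= 0)) # once complete, stays
  }
})

test_that("first-visit delays summarise whole days from first login", {
  roster <- data.frame(participant_id = c("p1", "p2", "p3"),
                       first_login = as.Date("2020-01-01"))
  mkv <- function(p, day) data.table::data.table(
    participant_id = p, module_id = "goal",
    start = as.POSIXct(sprintf("2020-01-01 12:00:00"), tz = "UTC") +
      day * 86400, duration_s = 300, visit_index = 1L)

  one <- first_visit_delay(mkv("p1", 55), roster)
  expect_equal(one$summary$median_days, 55)
  expect_equal(one$summary$q1_days, 55)
  expect_equal(one$summary$q3_days, 55)

  three <- first_visit_delay(
    data.table::rbindlist(list(mkv("p1", 48), mkv("p2", 55), mkv("p3", 64))),
    roster)
  expect_equal(three$summary$median_days, 55)
  expect_equal(three$summary$n, 3L)

  empty <- first_visit_delay(mkv("p1", 10)[0], roster)
  expect_equal(nrow(empty$summary), 0L)

  # only the earliest visit per participant-module counts
  twice <- first_visit_delay(
    data.table::rbindlist(list(mkv("p1", 20), mkv("p1", 90))), roster)
  expect_equal(twice$summary$median_days, 20)
})

test_that("visits dated before first login are excluded as data errors", {
  roster <- data.frame(participant_id = "p1",
                       first_login = as.Date("2020-06-01"))
  v <- data.table::data.table(
    participant_id = "p1", module_id = "goal",
    start = as.POSIXct("2020-05-20 10:00:00", tz = "UTC"),
    duration_s = 300, visit_index = 1L)
  expect_warning(res <- first_visit_delay(v, roster), "before first login")
  expect_equal(res$summary[module_id == "goal"]$n, 0L)
  expect_true(is.na(res$summary[module_id == "goal"]$median_days))
  expect_error(first_visit_delay(v, roster[0, ]), "absent from roster")
})

test_that("parser round-trips generated cohorts: counts, durations, unclosed visits", {
  for (seed in c(5, 6)) {
    co <- generate_cohort(small_cohort_config(n = 50, seed = seed))
    v <- parse_events(co$events)
    gt <- co$ground_truth$visits
    expect_equal(nrow(v), nrow(gt))
    m <- merge(v, gt, by = c("participant_id", "module_id", "visit_index"))
    expect_equal(nrow(m), nrow(gt))
    closed <- !m$missing_end
    expect_equal(m$duration_s.x[closed], m$duration_s.y[closed],
                 tolerance = 1e-6)
    # unclosed-visit conservation
    expect_equal(sum(is.na(m$duration_s.x)), sum(gt$missing_end))
    expect_true(all(is.na(m$duration_s.x) == m$missing_end))
    # classification agrees with ground truth
    cv <- classify_completion(v, default_module_specs())
    m2 <- merge(cv, gt, by = c("participant_id", "module_id", "visit_index"))
    expect_equal(m2$complete, m2$true_complete)
  }
})
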