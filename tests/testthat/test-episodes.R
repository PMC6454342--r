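test_that("screen on/off pairs become use intervals with QC-counted anomalies", {
  ev <- make_events("u1",
                    c("2020-05-05 10:00:00", "2020-05-05 10:05:00"),
                    c("screen_on", "screen_off"))
  iv <- pair_screen_events(ev)
  expect_equal(nrow(iv), 1)
  expect_equal(as.numeric(iv$end - iv$start, units = "secs"), 300)
  expect_equal(sum(attr(iv, "qc")$n), 0L)

  # a later screen_on supersedes an unmatched earlier one
  ev <- make_events("u1",
                    c("2020-05-05 10:00:00", "2020-05-05 10:02:00",
                      "2020-05-05 10:05:00"),
                    c("screen_on", "screen_on", "screen_off"))
  iv <- pair_screen_events(ev)
  expect_equal(format(iv$start, "%H:%M:%S"), "10:02:00")
  qc <- attr(iv, "qc")
  expect_equal(qc$n[qc$anomaly == "superseded_on"], 1L)

  # orphan screen_off produces no interval
  ev <- make_events("u1", "2020-05-05 09:00:00", "screen_off")
  iv <- pair_screen_events(ev)
  expect_equal(nrow(iv), 0)
  qc <- attr(iv, "qc")
  expect_equal(qc$n[qc$anomaly == "orphan_off"], 1L)

  # zero-length interval dropped and counted
  ev <- make_events("u1", rep("2020-05-05 10:00:00", 2),
                    c("screen_on", "screen_off"))
  iv <- pair_screen_events(ev)
  expect_equal(nrow(iv), 0)
  expect_equal(attr(iv, "qc")$n[4], 1L)
})

test_that("pairing never mixes users and keeps intervals ordered", {
  set.seed(11)
  base <- utc("2020-05-05 00:00:00")
  ev <- dplyr::bind_rows(lapply(c("a", "b", "c"), function(u) {
    t <- base + sort(runif(40, 0, 86400))
    make_events(u, format(t, "%Y-%m-%d %H:%M:%OS3"),
                rep(c("screen_on", "screen_off"), 20))
  }))
  iv <- pair_screen_events(ev)
  expect_equal(nrow(iv), 60)
  by_user <- split(iv, iv$user_id)
  for (b in by_user) {
    expect_true(all(diff(as.numeric(b$start)) > 0))
    expect_true(all(as.numeric(b$end) > as.numeric(b$start)))
    expect_true(all(as.numeric(b$start)[-1] >= as.numeric(b$end)[-nrow(b)]))
  }
})

test_that("the 60-second notification rule separates proactive from reactive", {
  iv <- make_intervals("2020-05-05 10:00:00", "2020-05-05 10:05:00")
  notif <- function(when) tibble::tibble(user_id = "u1", timestamp = utc(when))

  # 30 s before screen-on: reactive
  expect_false(classify_proactive(iv, notif("2020-05-05 09:59:30"))$proactive)
  # 61 s before: outside the window, proactive
  expect_true(classify_proactive(iv, notif("2020-05-05 09:58:59"))$proactive)
  # exactly 60 s before: window is closed on the left, reactive
  expect_false(classify_proactive(iv, notif("2020-05-05 09:59:00"))$proactive)
  # exactly at screen-on: not "before", proactive
  expect_true(classify_proactive(iv, notif("2020-05-05 10:00:00"))$proactive)
  # no notifications at all: proactive
  expect_true(classify_proactive(iv, notif(character(0)))$proactive)
  # notification for another user does not count
  other <- tibble::tibble(user_id = "u2", timestamp = utc("2020-05-05 09:59:30"))
  expect_true(classify_proactive(iv, other)$proactive)
})

test_that("enlarging the window only ever flips proactive to reactive", {
  set.seed(42)
  base <- as.numeric(utc("2020-05-05 00:00:00"))
  starts <- base + sort(runif(50, 0, 80000))
  iv <- make_intervals(
    format(as.POSIXct(starts, origin = "1970-01-01", tz = "UTC")),
    format(as.POSIXct(starts + 30, origin = "1970-01-01", tz = "UTC"))
  )
  notif <- tibble::tibble(
    user_id = "u1",
    timestamp = as.POSIXct(base + sort(runif(80, 0, 80000)),
                           origin = "1970-01-01", tz = "UTC")
  )
  prev <- classify_proactive(iv, notif, window = 1)$proactive
  for (w in c(10, 60, 300, 3600)) {
    cur <- classify_proactive(iv, notif, window = w)$proactive
    expect_true(all(cur <= prev))  # monotone: TRUE can only become FALSE
    prev <- cur
  }
})

test_that("use crossing midnight is split between the two days", {
  iv <- make_intervals("2020-05-05 23:50:00", "2020-05-06 00:10:00")
  days <- build_day_sequences(iv, no_exclusion_config())
  use <- days[days$kind == "use", ]
  expect_equal(nrow(use), 2)
  expect_equal(use$date, as.Date(c("2020-05-05", "2020-05-06")))
  expect_equal(use$duration, c(600, 600))
})

test_that("gaps become nonuse episodes bounded by midnight", {
  iv <- make_intervals(c("2020-05-05 09:00:00", "2020-05-05 10:00:00"),
                       c("2020-05-05 09:10:00", "2020-05-05 10:05:00"))
  days <- build_day_sequences(iv, no_exclusion_config())
  expect_equal(days$kind, c("nonuse", "use", "nonuse", "use", "nonuse"))
  expect_equal(days$duration[2:4], c(600, 3000, 300))
  # leading and trailing nonuse bounded by midnight
  expect_equal(days$duration[1], 9 * 3600)
  expect_equal(sum(days$duration), 86400)
})

test_that("first and last calendar days are excluded when configured", {
  iv <- make_intervals(
    c("2020-05-05 12:00:00", "2020-05-06 12:00:00", "2020-05-07 12:00:00"),
    c("2020-05-05 12:10:00", "2020-05-06 12:10:00", "2020-05-07 12:10:00")
  )
  days <- build_day_sequences(iv, study_config(exclude_first_last_day = TRUE))
  expect_equal(unique(days$date), as.Date("2020-05-06"))
  days_all <- build_day_sequences(iv, no_exclusion_config())
  expect_setequal(as.character(unique(days_all$date)),
                  c("2020-05-05", "2020-05-06", "2020-05-07"))
})

test_that("days with no use inside a span become full-day nonuse", {
  iv <- make_intervals(c("2020-05-05 12:00:00", "2020-05-07 12:00:00"),
                       c("2020-05-05 12:10:00", "2020-05-07 12:10:00"))
  days <- build_day_sequences(iv, no_exclusion_config())
  mid <- days[days$date == as.Date("2020-05-06"), ]
  expect_equal(nrow(mid), 1)
  expect_equal(mid$kind, "nonuse")
  expect_equal(mid$duration, 86400)
})

test_that("sleep policies flag the right nonuse time", {
  # uses 00:30-01:00 and 06:00-06:10, so nonuse is 00:00-00:30,
  # 01:00-06:00, and 06:10-24:00
  iv <- make_intervals(c("2020-05-05 00:30:00", "2020-05-05 06:00:00"),
                       c("2020-05-05 01:00:00", "2020-05-05 06:10:00"))
  days <- build_day_sequences(iv, no_exclusion_config())

  # none: identity
  expect_identical(apply_sleep_exclusion(days, sleep_policy("none")), days)

  # fixed window 00:00-07:00: the nonuse 01:00-06:00 falls fully inside
  fw <- sleep_policy("fixed_window", night_start = "00:00", night_end = "07:00")
  out <- apply_sleep_exclusion(days, fw)
  mid <- out[out$kind == "nonuse" & format(out$start, "%H:%M") == "01:00", ]
  expect_equal(nrow(mid), 1)
  expect_true(mid$sleep_excluded)
  expect_equal(mid$duration, 5 * 3600)
  # the trailing episode is split at the 07:00 boundary
  part_in <- out[out$kind == "nonuse" & format(out$start, "%H:%M") == "06:10", ]
  expect_equal(part_in$duration, 50 * 60)
  expect_true(part_in$sleep_excluded)
  part_out <- out[out$kind == "nonuse" & format(out$start, "%H:%M") == "07:00", ]
  expect_equal(part_out$duration, 17 * 3600)
  expect_false(part_out$sleep_excluded)
  expect_true(all(is.na(out$sleep_excluded[out$kind == "use"])))
  expect_equal(sum(out$duration), sum(days$duration))

  # longest overnight gap: a long midday gap must not win over the true
  # overnight one
  iv2 <- make_intervals(c("2020-05-05 07:30:00", "2020-05-05 20:00:00"),
                        c("2020-05-05 08:00:00", "2020-05-05 20:30:00"))
  days2 <- build_day_sequences(iv2, no_exclusion_config())
  lg <- sleep_policy("longest_overnight_gap", min_hours = 4)
  out2 <- apply_sleep_exclusion(days2, lg)
  flagged <- out2[out2$sleep_excluded %in% TRUE, ]
  expect_equal(nrow(flagged), 1)
  expect_equal(format(flagged$start, "%H:%M"), "00:00")
  expect_equal(flagged$duration, 7.5 * 3600)
  # below min_hours nothing is flagged
  lg18 <- sleep_policy("longest_overnight_gap", min_hours = 18)
  expect_false(any(apply_sleep_exclusion(days2, lg18)$sleep_excluded %in% TRUE))
})

test_that("durations are conserved by splitting and sleep exclusion", {
  set.seed(99)
  co <- suppressWarnings(generate_cohort(cohort_spec(n_users = 3, n_weeks = 2, seed = 5)))
  days <- segment_episodes(co$events, no_exclusion_config())
  per_day <- dplyr::summarise(dplyr::group_by(days, user_id, date),
                              total = sum(duration), .groups = "drop")
  expect_true(all(abs(per_day$total - 86400) < 1e-6))

  # flagging sleep never changes total accounted time
  flagged <- apply_sleep_exclusion(days, sleep_policy("longest_overnight_gap"))
  expect_equal(sum(flagged$duration), sum(days$duration), tolerance = 1e-9)

  # alternation: never two use episodes adjacent within a day
  runs <- dplyr::mutate(
    dplyr::group_by(days, user_id, date),
    prev = dplyr::lag(kind)
  )
  expect_false(any(runs$kind == "use" & runs$prev == "use", na.rm = TRUE))
})
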