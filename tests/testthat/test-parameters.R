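test_that("daily counts and durations split total from proactive use", {
  day <- make_day(
    dur = c(3600, 600, 1200, 300, 3600),
    kind = c("nonuse", "use", "nonuse", "use", "nonuse"),
    proactive = c(NA, TRUE, NA, FALSE, NA)
  )
  dp <- daily_parameters(day, no_exclusion_config())
  expect_equal(dp$F, 2)
  expect_equal(dp$D, 900)
  expect_equal(dp$PF, 1)
  expect_equal(dp$PD, 600)

  # day with no use at all
  empty <- make_day(86400, "nonuse")
  dp0 <- daily_parameters(empty, no_exclusion_config())
  expect_equal(unlist(dp0[c("F", "D", "PF", "PD")]),
               c(F = 0, D = 0, PF = 0, PD = 0))
  expect_true(all(is.na(dp0[c("RMSSD", "SI", "CI")])))

  # all-proactive day: PF = F and PD = D
  allp <- make_day(c(100, 50, 200, 60, 300),
                   c("nonuse", "use", "nonuse", "use", "nonuse"),
                   proactive = TRUE)
  dpa <- daily_parameters(allp, no_exclusion_config())
  expect_equal(dpa$PF, dpa$F)
  expect_equal(dpa$PD, dpa$D)
})

test_that("rmssd matches its definition on hand-computed cases", {
  expect_equal(rmssd(c(10, 20, 30)), 10)
  expect_equal(rmssd(rep(42, 7)), 0)
  # alternating a,b,a,b,..: every successive difference is |a-b|
  expect_identical(rmssd(rep(c(17, 60), 5)), 43)
  expect_true(is.na(rmssd(5)))
  expect_true(is.na(rmssd(numeric(0))))
})

test_that("similarity and control indices match hand-computed cases", {
  k4 <- c("nonuse", "use", "use", "use")
  expect_equal(similarity_index(c(100, 100, 100, 100), k4), 0)
  expect_equal(similarity_index(c(100, 90, 100, 110), k4), 20 / 3)
  expect_equal(control_index(c(30, 10, 10, 10), k4), 0)
  expect_equal(control_index(c(100, 10, 20, 30), k4), 40)

  # no nonuse episode with 3 following uses: undefined
  expect_true(is.na(similarity_index(c(100, 90, 100), c("nonuse", "use", "use"))))
  expect_true(is.na(control_index(c(90, 100, 80), c("use", "nonuse", "use"))))

  # a day where every eligible nonuse equals the sum of its 3 followers
  dur <- c(60, 10, 20, 30, 5)
  kind <- c("nonuse", "use", "use", "use", "nonuse")
  expect_equal(control_index(dur, kind), 0)
})

test_that("kernels agree with brute-force loops on random sequences", {
  set.seed(2203)
  for (i in 1:200) {
    n <- sample(0:40, 1)
    sq <- random_alternating(n, start_use = sample(c(TRUE, FALSE), 1))
    expect_equal(rmssd(sq$dur), rmssd_bf(sq$dur), tolerance = 1e-12)
    expect_equal(similarity_index(sq$dur, sq$kind), si_bf(sq$dur, sq$kind),
                 tolerance = 1e-12)
    expect_equal(similarity_index(sq$dur, sq$kind, denominator = "triplet_means"),
                 si_bf(sq$dur, sq$kind, denominator = "triplet_means"),
                 tolerance = 1e-12)
    expect_equal(control_index(sq$dur, sq$kind), ci_bf(sq$dur, sq$kind),
                 tolerance = 1e-12)
  }
})

test_that("the vectorized daily pipeline agrees with the sequence kernels", {
  set.seed(404)
  cfg <- no_exclusion_config()
  days <- dplyr::bind_rows(lapply(1:60, function(i) {
    n <- sample(2:30, 1)
    sq <- random_alternating(n)
    make_day(sq$dur, sq$kind, date = as.Date("2020-01-01") + (i - 1) %% 10,
             user_id = paste0("u", (i - 1) %/% 10))
  }))
  dp <- daily_parameters(days, cfg)
  for (r in sample(nrow(dp), 20)) {
    d <- days[days$user_id == dp$user_id[r] & days$date == dp$date[r], ]
    d <- d[order(d$start), ]
    expect_equal(dp$RMSSD[r], rmssd(d$duration), tolerance = 1e-12)
    expect_equal(dp$SI[r], similarity_index(d$duration, d$kind), tolerance = 1e-12)
    expect_equal(dp$CI[r], control_index(d$duration, d$kind), tolerance = 1e-12)
  }
})

test_that("reciprocity statistics scale with time units but RMSSD ignores shifts", {
  set.seed(7)
  sq <- random_alternating(21)
  c_ <- 3.7
  expect_equal(rmssd(sq$dur * c_), c_ * rmssd(sq$dur))
  expect_equal(similarity_index(sq$dur * c_, sq$kind),
               c_ * similarity_index(sq$dur, sq$kind))
  expect_equal(control_index(sq$dur * c_, sq$kind),
               c_ * control_index(sq$dur, sq$kind))
  # adding a constant: RMSSD invariant, SI in general not, CI shifts
  # because a nonuse is compared with a *sum* of three uses
  expect_equal(rmssd(sq$dur + 100), rmssd(sq$dur))
  expect_false(isTRUE(all.equal(control_index(sq$dur + 100, sq$kind),
                                control_index(sq$dur, sq$kind))))
})

test_that("sleep exclusion bridging policies differ as documented", {
  # nonuse(1000) use(100) [sleep 30000] use(200) nonuse(500) use(300) ...
  dur <- c(1000, 100, 30000, 200, 500, 300, 400, 250, 600)
  kind <- c("nonuse", "use", "nonuse", "use", "nonuse", "use", "nonuse",
            "use", "nonuse")
  day <- make_day(dur, kind, proactive = TRUE)
  day$sleep_excluded[3] <- TRUE

  adj <- daily_parameters(day, no_exclusion_config())
  seg <- daily_parameters(day, no_exclusion_config(sleep_bridge = "segment"))

  # adjacent: the sequence simply omits the sleep episode
  kept_dur <- dur[-3]
  expect_equal(adj$RMSSD, rmssd(kept_dur))
  expect_equal(adj$SI, similarity_index(kept_dur, kind[-3]))

  # segment: differences never cross the removed gap
  d1 <- diff(dur[1:2]); d2 <- diff(dur[4:9])
  expect_equal(seg$RMSSD, sqrt((sum(d1^2) + sum(d2^2)) / (length(d1) + length(d2))))
  # first nonuse loses its triplet (only 1 use before the sleep gap)
  expect_equal(seg$SI, similarity_index(dur[4:9], kind[4:9]))
  # counts are unaffected by bridging
  expect_equal(adj[c("F", "D", "PF", "PD")], seg[c("F", "D", "PF", "PD")])
})

test_that("period summaries average only over defined days", {
  daily <- tibble::tibble(
    user_id = "u1",
    date = as.Date("2020-01-01") + 0:4,
    F = c(10, 20, 30, 40, 50), D = 1:5 * 1000,
    PF = c(5, 5, 5, 5, 5), PD = 1:5 * 100,
    RMSSD = c(100, NA, 300, NA, 200),
    SI = rep(NA_real_, 5), CI = 1:5
  )
  s <- summarize_period(daily)
  expect_equal(s$mean[s$parameter == "F"], 30)
  expect_equal(s$mean[s$parameter == "RMSSD"], 200)
  expect_equal(s$n_days[s$parameter == "RMSSD"], 3)
  expect_true(is.na(s$mean[s$parameter == "SI"]))
  expect_equal(s$n_days[s$parameter == "SI"], 0)

  # restricting to a window of weeks
  s2 <- summarize_period(dplyr::mutate(daily, date = as.Date("2020-01-01") + c(0, 1, 7, 8, 14)),
                         weeks = 1:2)
  expect_equal(s2$n_days[s2$parameter == "F"], 4)
  expect_error(summarize_period(daily, weeks = 40), "no days")
})
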