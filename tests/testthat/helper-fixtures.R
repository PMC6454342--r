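# small constructors for hand-built event streams and day sequences

utc <- function(x) as.POSIXct(x, tz = "UTC")

make_events <- function(user_id, timestamp, event_type) {
  tibble::tibble(user_id = user_id, timestamp = utc(timestamp),
                 event_type = event_type)
}

make_intervals <- function(start, end, user_id = "u1", proactive = NULL) {
  out <- tibble::tibble(user_id = user_id, start = utc(start), end = utc(end))
  if (!is.null(proactive)) out$proactive <- proactive
  out
}

# one-user day-sequence tibble from alternating durations starting at a
# given clock time; used to feed daily_parameters() directly
make_day <- function(dur, kind, date = as.Date("2020-05-05"),
                     start_clock = 8 * 3600, proactive = NA,
                     user_id = "u1") {
  start <- as.numeric(utc(paste(date))) + start_clock + cumsum(c(0, dur[-length(dur)]))
  tibble::tibble(
    user_id = user_id, date = date, kind = kind,
    start = as.POSIXct(start, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(start + dur, origin = "1970-01-01", tz = "UTC"),
    duration = dur,
    proactive = ifelse(kind == "use", proactive, NA),
    sleep_excluded = ifelse(kind == "nonuse", FALSE, NA)
  )
}

no_exclusion_config <- function(...) {
  study_config(sleep_policy = sleep_policy("none"),
               exclude_first_last_day = FALSE, ...)
}

# memoised Monte-Carlo cohorts shared across test files: daily parameters
# of an n_users x 8-week cohort at a given drift
mc_cache <- new.env(parent = emptyenv())

mc_daily <- function(rep, drift, n_users = 100) {
  key <- sprintf("r%d_d%s_n%d", rep, format(drift), n_users)
  if (is.null(mc_cache[[key]])) {
    spec <- cohort_spec(n_users = n_users, n_weeks = 8,
                        seed = 77000L + rep * 13L + round(drift * 10),
                        drift_sd_per_week = drift)
    co <- suppressWarnings(generate_cohort(spec))
    mc_cache[[key]] <- daily_from_events(
      co$events, study_config(exclude_first_last_day = FALSE)
    )
  }
  mc_cache[[key]]
}
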