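#' Pair screen-on/screen-off events into use intervals
#'
#' A use episode runs from a `screen_on` event to the next `screen_off` of
#' the same user. Device logs contain anomalies, which are resolved
#' deterministically and counted, never silently dropped:
#'
#' * a second `screen_on` before any `screen_off` supersedes the first
#'   (the later wake event wins) — counted as `superseded_on`;
#' * a `screen_off` with no prior unmatched `screen_on` is an orphan —
#'   counted as `orphan_off`;
#' * a trailing `screen_on` never followed by a `screen_off` — counted as
#'   `unmatched_on`;
#' * an interval whose on and off share a timestamp — dropped, counted as
#'   `zero_length`.
#'
#' @param events tibble from [read_screen_events()] (notification rows are
#'   ignored here).
#' @return tibble `user_id`, `start`, `end` of non-overlapping, ordered use
#'   intervals, with attribute `qc`: a tibble of anomaly counts.
#' @export
pair_screen_events <- function(events) {
  sc <- events[events$event_type %in% c("screen_on", "screen_off"), ]
  if (nrow(sc) == 0) {
    out <- tibble::tibble(
      user_id = character(),
      start = as.POSIXct(character(), tz = "UTC"),
      end = as.POSIXct(character(), tz = "UTC")
    )
    attr(out, "qc") <- qc_tibble(0L, 0L, 0L, 0L)
    return(out)
  }
  u <- sc$user_id
  is_on <- sc$event_type == "screen_on"
  # maximal runs of equal (user, type); consecutive runs within a user
  # necessarily alternate on/off
  n <- nrow(sc)
  new_run <- c(TRUE, u[-1] != u[-n] | is_on[-1] != is_on[-n])
  run_id <- cumsum(new_run)
  run_first <- which(new_run)
  run_last <- c(run_first[-1] - 1L, n)
  run_len <- run_last - run_first + 1L
  run_user <- u[run_first]
  run_on <- is_on[run_first]
  nr <- length(run_first)
  next_same_user <- c(run_user[-1] == run_user[-nr], FALSE)
  prev_same_user <- c(FALSE, run_user[-1] == run_user[-nr])

  matched <- run_on & next_same_user           # on-run followed by off-run
  superseded_on <- sum(run_len[matched] - 1L)
  unmatched_on <- sum(run_len[run_on & !next_same_user])
  # off-run: first event matches the preceding on-run (if any); the rest,
  # or all of a leading off-run, are orphans
  off_run <- !run_on
  orphan_off <- sum(run_len[off_run & prev_same_user] - 1L) +
    sum(run_len[off_run & !prev_same_user])

  m_idx <- which(matched)
  start <- sc$timestamp[run_last[m_idx]]          # latest on of the on-run
  end <- sc$timestamp[run_first[m_idx + 1L]]      # first off of the off-run
  keep <- as.numeric(end) > as.numeric(start)
  zero_length <- sum(!keep)
  out <- tibble::tibble(
    user_id = run_user[m_idx][keep],
    start = start[keep],
    end = end[keep]
  )
  attr(out, "qc") <- qc_tibble(superseded_on, orphan_off, unmatched_on, zero_length)
  out
}

qc_tibble <- function(superseded_on, orphan_off, unmatched_on, zero_length) {
  tibble::tibble(
    anomaly = c("superseded_on", "orphan_off", "unmatched_on", "zero_length"),
    n = as.integer(c(superseded_on, orphan_off, unmatched_on, zero_length))
  )
}

#' Classify use intervals as proactive or reactive
#'
#' A use episode is *reactive* when at least one notification arrived in
#' the window before screen-on (by default the 60 seconds immediately
#' preceding it), and *proactive* (self-initiated) otherwise. The window is
#' half-open, `[start - window, start)`: a notification exactly `window`
#' seconds before screen-on counts, one exactly at screen-on does not (the
#' screen is already turning on).
#'
#' Enlarging `window` can only flip episodes from proactive to reactive,
#' never the reverse.
#'
#' @param intervals tibble of use intervals (`user_id`, `start`, `end`).
#' @param notifications either the full event tibble (its `notification`
#'   rows are used) or a tibble of `user_id`, `timestamp`.
#' @param window seconds before screen-on scanned for notifications.
#' @return `intervals` with a logical `proactive` column added.
#' @export
classify_proactive <- function(intervals, notifications, window = 60) {
  stopifnot(window > 0)
  if ("event_type" %in% names(notifications)) {
    notifications <- notifications[notifications$event_type == "notification", ]
  }
  s <- as.numeric(intervals$start)
  out <- intervals
  if (nrow(intervals) == 0) {
    out$proactive <- logical(0)
    return(out)
  }
  nt <- split(as.numeric(notifications$timestamp), notifications$user_id)
  pro <- rep(TRUE, nrow(intervals))
  for (uid in unique(intervals$user_id)) {
    t <- sort(nt[[uid]])
    if (length(t) == 0) next
    i <- which(intervals$user_id == uid)
    # count notifications with start - window <= t < start
    n_in <- findInterval(s[i], t, left.open = TRUE) -
      findInterval(s[i] - window, t, left.open = TRUE)
    pro[i] <- n_in == 0
  }
  out$proactive <- pro
  out
}

# local day index (days since 1970-01-01 in tz) and numeric midnight
local_daynum <- function(num, tz) {
  if (tz == "UTC") {
    floor(num / 86400)
  } else {
    lt <- as.POSIXlt(as.POSIXct(num, origin = "1970-01-01", tz = "UTC"), tz = tz)
    as.integer(as.Date(lt))
  }
}

day_start_num <- function(day, tz) {
  if (tz == "UTC") {
    day * 86400
  } else {
    ud <- sort(unique(day))
    m <- as.numeric(as.POSIXct(paste(as.Date(ud, origin = "1970-01-01")), tz = tz))
    m[match(day, ud)]
  }
}

#' Build daily alternating use/nonuse sequences
#'
#' Splits use intervals at local midnight (so daily totals are bounded by
#' 86,400 s), materializes the gaps between uses — including the leading
#' gap from midnight to the first use and the trailing gap to the next
#' midnight — as nonuse episodes, and (by default) drops each user's first
#' and last calendar day, whose records are typically incomplete. Calendar
#' days inside a user's span with no use at all become a single full-day
#' nonuse episode. All intervals are half-open `[start, end)`.
#'
#' A use interval that crosses midnight contributes one (shorter) use
#' episode to each day, both inheriting the original episode's proactive
#' flag.
#'
#' @param intervals use intervals (`user_id`, `start`, `end`, optionally
#'   `proactive`), ordered and non-overlapping per user.
#' @param config a [study_config()]; uses `tz` and
#'   `exclude_first_last_day`.
#' @return episode tibble: `user_id`, `date`, `kind` (`"use"`/`"nonuse"`),
#'   `start`, `end`, `duration` (s), `proactive` (`NA` for nonuse),
#'   `sleep_excluded` (`FALSE` for nonuse until [apply_sleep_exclusion()]
#'   runs; `NA` for use). Within each day no two use episodes are
#'   adjacent.
#' @export
build_day_sequences <- function(intervals, config = study_config()) {
  tz <- config$tz
  if (nrow(intervals) == 0) return(empty_day_sequence())
  s <- as.numeric(intervals$start)
  e <- as.numeric(intervals$end)
  pro <- if ("proactive" %in% names(intervals)) intervals$proactive else rep(NA, nrow(intervals))
  ok <- e > s
  s <- s[ok]; e <- e[ok]; pro <- pro[ok]; uid <- intervals$user_id[ok]

  ds <- local_daynum(s, tz)
  de <- local_daynum(e - 1e-4, tz)  # end-exclusive: an end exactly at
  np <- de - ds + 1L                # midnight belongs to the earlier day
  idx <- rep(seq_along(s), np)
  day <- ds[idx] + (sequence(np) - 1L)
  mid <- day_start_num(day, tz)
  nxt <- day_start_num(day + 1L, tz)
  use <- tibble::tibble(
    user_id = uid[idx], day = day,
    start = pmax(s[idx], mid), end = pmin(e[idx], nxt),
    mid = mid, nxt = nxt, proactive = pro[idx]
  )
  use <- use[use$end > use$start, ]
  use <- use[order(use$user_id, use$start, method = "radix"), ]
  nu <- nrow(use)

  # per-user span of calendar days, including days without any use
  new_user <- c(TRUE, use$user_id[-1] != use$user_id[-nu])
  user_last <- c(new_user[-1], TRUE)
  span <- tibble::tibble(user_id = use$user_id[new_user],
                         d0 = use$day[new_user], d1 = use$day[user_last])
  all_days <- tidyr::unnest(
    dplyr::mutate(span, day = purrr::map2(.data$d0, .data$d1, seq)),
    "day"
  )[c("user_id", "day")]

  # gaps between uses (and from midnight to the first use / to the next
  # midnight); intervals are sorted and non-overlapping, so the last row
  # of each user-day has the day's max end
  new_day <- new_user | c(TRUE, use$day[-1] != use$day[-nu])
  day_last <- c(new_day[-1], TRUE)
  gap_start <- c(NA_real_, use$end[-nu])
  gap_start[new_day] <- use$mid[new_day]
  nonuse_mid <- tibble::tibble(user_id = use$user_id, day = use$day,
                               start = gap_start, end = use$start)
  trailing <- tibble::tibble(user_id = use$user_id[day_last],
                             day = use$day[day_last],
                             start = use$end[day_last], end = use$nxt[day_last])
  empty_days <- dplyr::anti_join(all_days, use[c("user_id", "day")],
                                 by = c("user_id", "day"))
  empty_days$start <- day_start_num(empty_days$day, tz)
  empty_days$end <- day_start_num(empty_days$day + 1L, tz)
  nonuse <- dplyr::bind_rows(nonuse_mid, trailing, empty_days)
  nonuse <- nonuse[nonuse$end > nonuse$start, ]
  episodes <- dplyr::bind_rows(
    tibble::tibble(user_id = use$user_id, day = use$day, kind = "use",
                   start = use$start, end = use$end,
                   proactive = use$proactive, sleep_excluded = NA),
    tibble::tibble(user_id = nonuse$user_id, day = nonuse$day, kind = "nonuse",
                   start = nonuse$start, end = nonuse$end,
                   proactive = NA, sleep_excluded = FALSE)
  )
  episodes <- dplyr::arrange(episodes, .data$user_id, .data$start, .data$kind == "use")

  if (config$exclude_first_last_day) {
    episodes <- dplyr::filter(
      dplyr::left_join(episodes, span, by = "user_id"),
      .data$day > .data$d0, .data$day < .data$d1
    )
    episodes$d0 <- episodes$d1 <- NULL
  }

  tibble::tibble(
    user_id = episodes$user_id,
    date = as.Date(episodes$day, origin = "1970-01-01"),
    kind = episodes$kind,
    start = as.POSIXct(episodes$start, origin = "1970-01-01", tz = tz),
    end = as.POSIXct(episodes$end, origin = "1970-01-01", tz = tz),
    duration = episodes$end - episodes$start,
    proactive = as.logical(episodes$proactive),
    sleep_excluded = as.logical(episodes$sleep_excluded)
  )
}

empty_day_sequence <- function() {
  tibble::tibble(
    user_id = character(), date = as.Date(character()), kind = character(),
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    duration = numeric(), proactive = logical(), sleep_excluded = logical()
  )
}

# overlap (seconds) of [s, e) seconds-of-day with a clock region that may
# span midnight
night_overlap <- function(s, e, a, b) {
  if (a <= b) {
    pmax(0, pmin(e, b) - pmax(s, a))
  } else {
    pmax(0, pmin(e, b) - pmax(s, 0)) + pmax(0, pmin(e, 86400) - pmax(s, a))
  }
}

#' Flag sleeping time inside nonuse episodes
#'
#' Sleep must not count as voluntary nonuse, so the reciprocity statistics
#' exclude it. Depending on the [sleep_policy()]:
#'
#' * `"none"`: returns the input unchanged;
#' * `"fixed_window"`: the parts of nonuse episodes inside the clock window
#'   are flagged; partially overlapping episodes are split so exactly the
#'   overlapping part is flagged (a day may then contain consecutive
#'   nonuse pieces);
#' * `"longest_overnight_gap"`: per day, the longest nonuse episode
#'   overlapping the night region is flagged in full when it lasts at
#'   least `min_hours` hours.
#'
#' Use episodes are never flagged.
#'
#' @param days day-sequence tibble from [build_day_sequences()].
#' @param policy a [sleep_policy()].
#' @param tz timezone for clock arithmetic (match the config used to build
#'   the days).
#' @return the day-sequence tibble with `sleep_excluded` set (and episodes
#'   possibly split under `"fixed_window"`).
#' @export
apply_sleep_exclusion <- function(days, policy = sleep_policy(), tz = "UTC") {
  if (!inherits(policy, "sleep_policy")) stop("unknown sleep policy", call. = FALSE)
  if (policy$policy == "none" || nrow(days) == 0) return(days)

  daynum <- as.integer(days$date)
  mid <- day_start_num(daynum, tz)
  sod_s <- as.numeric(days$start) - mid
  sod_e <- as.numeric(days$end) - mid
  nonuse <- days$kind == "nonuse"

  if (policy$policy == "longest_overnight_gap") {
    ov <- night_overlap(sod_s, sod_e, policy$night_start, policy$night_end)
    cand <- nonuse & ov > 0 & days$duration >= policy$min_hours * 3600
    tbl <- tibble::tibble(row = seq_len(nrow(days)),
                          user_id = days$user_id, date = days$date,
                          overlap = ov)[cand, ]
    if (nrow(tbl) > 0) {
      # the day's sleep bout: the gap most contained in the night window
      pick <- dplyr::slice_max(dplyr::group_by(tbl, .data$user_id, .data$date),
                               .data$overlap, n = 1, with_ties = FALSE)
      days$sleep_excluded[pick$row] <- TRUE
    }
    return(days)
  }

  # fixed_window: split nonuse episodes at the window boundaries
  a <- policy$night_start; b <- policy$night_end
  cuts <- if (a <= b) c(a, b) else c(b, a)
  rows <- vector("list", nrow(days))
  in_window <- function(x) if (a <= b) x >= a & x < b else x < b | x >= a
  for (i in seq_len(nrow(days))) {
    if (!nonuse[i]) { rows[[i]] <- days[i, ]; next }
    bounds <- sort(unique(c(sod_s[i], sod_e[i], cuts[cuts > sod_s[i] & cuts < sod_e[i]])))
    piece_s <- utils::head(bounds, -1); piece_e <- bounds[-1]
    piece <- days[rep(i, length(piece_s)), ]
    piece$start <- days$start[i] + (piece_s - sod_s[i])
    piece$end <- days$start[i] + (piece_e - sod_s[i])
    piece$duration <- piece_e - piece_s
    piece$sleep_excluded <- in_window((piece_s + piece_e) / 2)
    rows[[i]] <- piece
  }
  dplyr::bind_rows(rows)
}

#' Segment an event log into daily episode sequences
#'
#' Convenience pipeline: [pair_screen_events()], [classify_proactive()],
#' [build_day_sequences()], [apply_sleep_exclusion()].
#'
#' @param events event tibble from [read_screen_events()] or
#'   [generate_cohort()].
#' @param config a [study_config()].
#' @return day-sequence tibble with the pairing QC counts attached as
#'   attribute `qc`.
#' @export
segment_episodes <- function(events, config = study_config()) {
  intervals <- pair_screen_events(events)
  qc <- attr(intervals, "qc")
  intervals <- classify_proactive(intervals, events, window = config$proactive_window)
  days <- build_day_sequences(intervals, config)
  days <- apply_sleep_exclusion(days, config$sleep_policy, tz = config$tz)
  attr(days, "qc") <- qc
  days
}
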