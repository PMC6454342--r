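#' Root mean square of successive differences of episode durations
#'
#' With `A_1 .. A_n` the durations of a day's alternating use/nonuse
#' episodes (sleep excluded) in temporal order, the RMSSD is
#' `sqrt( sum_{i=1}^{n-1} (A_{i+1} - A_i)^2 / (n-1) )`. Low values mean
#' adjacent use and nonuse episodes have similar lengths (high use/nonuse
#' reciprocity). Undefined (`NA`) when fewer than two episodes remain.
#'
#' @param durations numeric vector of episode durations in temporal order.
#' @return RMSSD in the units of `durations`, or `NA`.
#' @export
#' @examples
#' rmssd(c(10, 20, 30)) # sqrt((100 + 100) / 2) = 10
rmssd <- function(durations) {
  durations <- durations[!is.na(durations)]
  if (length(durations) < 2) return(NA_real_)
  d <- diff(durations)
  sqrt(sum(d^2) / length(d))
}

# shared triplet bookkeeping for SI and CI: for each nonuse episode, the
# durations of the k use episodes that follow it within the sequence
lookahead_uses <- function(durations, kinds, k) {
  stopifnot(length(durations) == length(kinds), k >= 1)
  use_dur <- durations[kinds == "use"]
  cum_use <- cumsum(kinds == "use")
  x_idx <- which(kinds == "nonuse")
  if (length(x_idx) == 0) return(NULL)
  first_follow <- cum_use[x_idx] + 1L
  eligible <- first_follow + k - 1L <= length(use_dur)
  x_idx <- x_idx[eligible]
  if (length(x_idx) == 0) return(NULL)
  y <- vapply(seq_len(k) - 1L,
              function(j) use_dur[cum_use[x_idx] + 1L + j],
              numeric(length(x_idx)))
  list(x = durations[x_idx], y = matrix(y, nrow = length(x_idx)))
}

#' Similarity Index of a day's use/nonuse sequence
#'
#' Each nonuse episode `X_i` is compared with its `k` (default 3)
#' following use episodes `Y_i, Y_{i+1}, ..`: the SI is the average of the
#' absolute differences `|X_i - Y_j|`. Nonuse episodes with fewer than `k`
#' following uses in the day are skipped; with no eligible nonuse episode
#' the SI is undefined (`NA`). Low values mean nonuse episodes resemble
#' the uses that follow them.
#'
#' @param durations,kinds episode durations and kinds (`"use"`/`"nonuse"`)
#'   in temporal order, sleep already excluded.
#' @param k number of following use episodes per nonuse episode.
#' @param denominator `"all_diffs"` (default) averages over all `k * n`
#'   differences; `"triplet_means"` averages the per-nonuse-episode means.
#'   With every eligible episode contributing exactly `k` differences the
#'   two coincide; the switch matters only for generalizations with
#'   ragged look-ahead.
#' @return SI in duration units, or `NA`.
#' @export
#' @examples
#' similarity_index(c(100, 90, 100, 110), c("nonuse", "use", "use", "use"))
similarity_index <- function(durations, kinds, k = 3,
                             denominator = c("all_diffs", "triplet_means")) {
  denominator <- match.arg(denominator)
  la <- lookahead_uses(durations, kinds, k)
  if (is.null(la)) return(NA_real_)
  ad <- abs(la$x - la$y)
  if (denominator == "all_diffs") mean(ad) else mean(rowMeans(ad))
}

#' Control Index of a day's use/nonuse sequence
#'
#' Each nonuse episode `X_i` is compared with the *total* of its `k`
#' (default 3) following use episodes: the CI is the average of
#' `|X_i - (Y_i + .. + Y_{i+k-1})|` over eligible nonuse episodes.
#' Proposed as an index of smartphone use-control ability. Undefined
#' (`NA`) when no nonuse episode has `k` following uses.
#'
#' @inheritParams similarity_index
#' @return CI in duration units, or `NA`.
#' @export
#' @examples
#' control_index(c(100, 10, 20, 30), c("nonuse", "use", "use", "use")) # 40
control_index <- function(durations, kinds, k = 3) {
  la <- lookahead_uses(durations, kinds, k)
  if (is.null(la)) return(NA_real_)
  mean(abs(la$x - rowSums(la$y)))
}

#' Compute the seven daily use parameters
#'
#' For every user-day in a day-sequence tibble, computes:
#'
#' * `F`, `D`: total use frequency (episode count) and duration (s);
#' * `PF`, `PD`: the same restricted to proactive episodes;
#' * `RMSSD`, `SI`, `CI`: use/nonuse reciprocity statistics (see
#'   [rmssd()], [similarity_index()], [control_index()]), computed after
#'   removing sleep-flagged nonuse episodes.
#'
#' Days with no use episodes get zero counts/durations; reciprocity
#' statistics are `NA` (undefined, not zero) on days with too few
#' episodes. How the removed sleep gap is handled is governed by
#' `config$sleep_bridge`: `"adjacent"` concatenates the remaining episodes
#' into one sequence (the removed gap's neighbours become adjacent),
#' `"segment"` never differences or pairs episodes across the removed gap
#' (numerators and denominators are then pooled over the day's segments).
#'
#' @param days day-sequence tibble from [segment_episodes()] (or
#'   [build_day_sequences()] + [apply_sleep_exclusion()]).
#' @param config a [study_config()]; uses `lookahead_k`, `si_denominator`,
#'   `sleep_bridge`.
#' @return tibble `user_id`, `date`, `F`, `D`, `PF`, `PD`, `RMSSD`, `SI`,
#'   `CI`, one row per user-day.
#' @export
daily_parameters <- function(days, config = study_config()) {
  if (nrow(days) == 0) {
    return(tibble::as_tibble(c(
      list(user_id = character(), date = as.Date(character())),
      setNames(rep(list(numeric()), 7), PARAM_NAMES)
    )))
  }
  days <- days[order(days$user_id, days$date, as.numeric(days$start),
                     method = "radix"), ]
  n <- nrow(days)
  new_day <- c(TRUE, days$user_id[-1] != days$user_id[-n] |
                 days$date[-1] != days$date[-n])
  gid <- cumsum(new_day)
  is_use <- days$kind == "use"
  is_pro <- is_use & days$proactive %in% TRUE
  counts <- tibble::tibble(
    user_id = days$user_id[new_day],
    date = days$date[new_day],
    F = unname(rowsum(as.integer(is_use), gid, reorder = FALSE)[, 1]),
    D = unname(rowsum(days$duration * is_use, gid, reorder = FALSE)[, 1]),
    PF = unname(rowsum(as.integer(is_pro), gid, reorder = FALSE)[, 1]),
    PD = unname(rowsum(days$duration * is_pro, gid, reorder = FALSE)[, 1])
  )

  flagged <- days$kind == "nonuse" & days$sleep_excluded %in% TRUE
  seg <- if (config$sleep_bridge == "segment") {
    # segment index = number of removed episodes seen so far in the day
    gcumsum(as.integer(flagged), new_day)
  } else {
    rep(0L, n)
  }
  kept <- tibble::tibble(
    gid = gid, kind = days$kind, duration = days$duration, seg = seg
  )[!flagged, ]

  recip <- reciprocity_stats(kept, config$lookahead_k, config$si_denominator)
  out <- counts
  out$RMSSD <- recip$RMSSD[match(seq_len(max(gid)), recip$gid)]
  out$SI <- recip$SI[match(seq_len(max(gid)), recip$gid)]
  out$CI <- recip$CI[match(seq_len(max(gid)), recip$gid)]
  out[c("user_id", "date", PARAM_NAMES)]
}

# Vectorized day-level RMSSD/SI/CI over an episode table (gid = day group,
# seg, kind, duration) in temporal order. Differences and look-ahead
# triplets never cross a segment boundary.
reciprocity_stats <- function(kept, k, denominator) {
  m <- nrow(kept)
  if (m == 0) return(tibble::tibble(gid = integer(), RMSSD = numeric(),
                                    SI = numeric(), CI = numeric()))
  new_seg <- c(TRUE, kept$gid[-1] != kept$gid[-m] | kept$seg[-1] != kept$seg[-m])
  sdiff <- c(NA_real_, diff(kept$duration))
  sdiff[new_seg] <- NA_real_
  ss <- unname(rowsum(ifelse(is.na(sdiff), 0, sdiff^2), kept$gid, reorder = FALSE)[, 1])
  nd <- unname(rowsum(as.integer(!is.na(sdiff)), kept$gid, reorder = FALSE)[, 1])
  out <- tibble::tibble(gid = unique(kept$gid))
  out$RMSSD <- ifelse(nd > 0, sqrt(ss / nd), NA_real_)

  # look-ahead: within a segment, nonuse row i is paired with the uses
  # indexed cum_use(i)+1 .. cum_use(i)+k
  is_use <- kept$kind == "use"
  cum_use <- gcumsum(as.integer(is_use), new_seg)
  sgid <- cumsum(new_seg)
  KEY <- 1e7  # max episodes per day-segment, far above anything physical
  use_key <- sgid[is_use] * KEY + cum_use[is_use]
  use_dur <- kept$duration[is_use]
  xi <- which(!is_use)
  x <- kept$duration[xi]
  ymat <- matrix(NA_real_, length(xi), k)
  for (j in seq_len(k)) {
    ymat[, j] <- use_dur[match(sgid[xi] * KEY + cum_use[xi] + j, use_key)]
  }
  eligible <- !is.na(ymat[, k])
  if (any(eligible)) {
    xg <- kept$gid[xi][eligible]
    si_sum <- rowSums(abs(x[eligible] - ymat[eligible, , drop = FALSE]))
    ci_ad <- abs(x[eligible] - rowSums(ymat[eligible, , drop = FALSE]))
    k_elig <- unname(rowsum(rep(1L, length(xg)), xg, reorder = FALSE)[, 1])
    sig <- as.integer(rownames(rowsum(rep(1L, length(xg)), xg, reorder = FALSE)))
    si <- if (denominator == "all_diffs") {
      unname(rowsum(si_sum, xg, reorder = FALSE)[, 1]) / (k * k_elig)
    } else {
      unname(rowsum(si_sum / k, xg, reorder = FALSE)[, 1]) / k_elig
    }
    ci <- unname(rowsum(ci_ad, xg, reorder = FALSE)[, 1]) / k_elig
    out$SI <- unname(si[match(out$gid, sig)])
    out$CI <- unname(ci[match(out$gid, sig)])
  } else {
    out$SI <- NA_real_
    out$CI <- NA_real_
  }
  out
}

#' Assign study weeks to daily records
#'
#' Week 1 starts at each user's first recorded day; `week = floor(days
#' since first day / 7) + 1`.
#'
#' @param daily daily-parameter tibble (needs `user_id`, `date`).
#' @return `daily` with an integer `week` column.
#' @export
add_week <- function(daily) {
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(daily, .data$user_id),
    week = as.integer(as.integer(.data$date - min(.data$date)) %/% 7L + 1L)
  ))
}

#' Average daily parameters over a window of weeks
#'
#' Per-user means of each daily parameter over the days where it is
#' defined (undefined days are dropped, never imputed as zero), with the
#' number of contributing days recorded per field.
#'
#' @param daily daily-parameter tibble from [daily_parameters()].
#' @param weeks optional integer vector of study weeks (see [add_week()])
#'   to restrict to; default uses all days.
#' @return long tibble `user_id`, `parameter`, `mean`, `n_days`.
#' @export
summarize_period <- function(daily, weeks = NULL) {
  if (!is.null(weeks)) {
    daily <- dplyr::filter(add_week(daily), .data$week %in% .env$weeks)
  }
  if (nrow(daily) == 0) stop("window covers no days", call. = FALSE)
  long <- tidyr::pivot_longer(daily[c("user_id", PARAM_NAMES)],
                              dplyr::all_of(PARAM_NAMES),
                              names_to = "parameter", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$user_id, .data$parameter),
    mean = if (any(!is.na(.data$value))) mean(.data$value, na.rm = TRUE) else NA_real_,
    n_days = sum(!is.na(.data$value)),
    .groups = "drop"
  )
  out$parameter <- factor(out$parameter, levels = PARAM_NAMES)
  dplyr::arrange(out, .data$user_id, .data$parameter)
}

#' End-to-end: event log to daily parameters
#'
#' Runs [segment_episodes()] then [daily_parameters()].
#'
#' @param events event tibble.
#' @param config a [study_config()].
#' @return daily-parameter tibble with the segmentation QC attached as
#'   attribute `qc`.
#' @export
daily_from_events <- function(events, config = study_config()) {
  days <- segment_episodes(events, config)
  out <- daily_parameters(days, config)
  attr(out, "qc") <- attr(days, "qc")
  out
}
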