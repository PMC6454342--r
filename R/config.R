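#' Sleep-exclusion policy
#'
#' Describes how sleeping time is identified so it can be excluded from
#' nonuse episodes before the reciprocity statistics are computed. Three
#' policies are supported:
#'
#' * `"none"`: no exclusion.
#' * `"fixed_window"`: everything between two local clock times (possibly
#'   spanning midnight) counts as sleep; nonuse episodes, or the parts of
#'   them inside the window, are flagged.
#' * `"longest_overnight_gap"`: per day, the longest nonuse episode that
#'   overlaps the night window (`night_start`--`night_end`, spanning
#'   midnight) is flagged in full, provided it lasts at least `min_hours`.
#'   This emulates detecting the main sleep bout from the use record itself.
#'
#' @param policy one of `"longest_overnight_gap"`, `"fixed_window"`, `"none"`.
#' @param min_hours minimum duration (hours) a gap must have to count as the
#'   sleep bout (`longest_overnight_gap` only).
#' @param night_start,night_end local clock times (`"HH:MM"`) bounding the
#'   night region in which the sleep bout is searched for, or the fixed
#'   window itself for `"fixed_window"`.
#' @return a `sleep_policy` list.
#' @export
#' @examples
#' sleep_policy("fixed_window", night_start = "00:00", night_end = "07:00")
sleep_policy <- function(policy = c("longest_overnight_gap", "fixed_window", "none"),
                         min_hours = 4,
                         night_start = "21:00",
                         night_end = "11:00") {
  policy <- match.arg(policy)
  stopifnot(min_hours > 0)
  structure(
    list(
      policy = policy,
      min_hours = min_hours,
      night_start = parse_clock(night_start),
      night_end = parse_clock(night_end)
    ),
    class = "sleep_policy"
  )
}

# "HH:MM" or "HH:MM:SS" -> seconds since local midnight
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (any(is.na(parts)) || length(parts) < 2 || length(parts) > 3) {
    stop("clock time must be 'HH:MM' or 'HH:MM:SS', got ", x, call. = FALSE)
  }
  sum(parts * c(3600, 60, 1)[seq_along(parts)])
}

#' Study configuration
#'
#' Bundles the tunable constants of the pipeline. Defaults follow the
#' published analysis protocol: a 60-second pre-onset notification window
#' for the proactive/reactive distinction, exclusion of each user's first
#' and last calendar day, a look-ahead of 3 use episodes for the Similarity
#' and Control Indices, and 0.75 as the "high correlation" criterion.
#'
#' @param proactive_window seconds before screen-on in which a notification
#'   makes the episode reactive. Default 60.
#' @param sleep_policy a [sleep_policy()] object.
#' @param lookahead_k number of use episodes following a nonuse episode used
#'   by the Similarity and Control Indices. Default 3.
#' @param high_corr_threshold Pearson r at or above which a stability
#'   correlation is flagged "high". Default 0.75.
#' @param exclude_first_last_day drop each user's first and last calendar
#'   day (their data are typically incomplete). Default `TRUE`.
#' @param tz IANA timezone used for day assignment (local midnight).
#' @param si_denominator `"all_diffs"` averages the Similarity Index over
#'   all 3k absolute differences; `"triplet_means"` averages per-nonuse
#'   triplet means. The two coincide when every nonuse episode has a full
#'   triplet of following uses.
#' @param sleep_bridge after removing sleep-flagged episodes, `"adjacent"`
#'   treats the remaining episodes as consecutive for the reciprocity
#'   statistics; `"segment"` never differences or pairs across the removed
#'   gap.
#' @param rng_seed optional integer seed recorded with the configuration.
#' @return a `study_config` list.
#' @export
study_config <- function(proactive_window = 60,
                         sleep_policy = screenuse::sleep_policy(),
                         lookahead_k = 3,
                         high_corr_threshold = 0.75,
                         exclude_first_last_day = TRUE,
                         tz = "UTC",
                         si_denominator = c("all_diffs", "triplet_means"),
                         sleep_bridge = c("adjacent", "segment"),
                         rng_seed = NULL) {
  stopifnot(
    proactive_window > 0,
    lookahead_k >= 1,
    high_corr_threshold > 0, high_corr_threshold < 1
  )
  structure(
    list(
      proactive_window = proactive_window,
      sleep_policy = sleep_policy,
      lookahead_k = as.integer(lookahead_k),
      high_corr_threshold = high_corr_threshold,
      exclude_first_last_day = isTRUE(exclude_first_last_day),
      tz = tz,
      si_denominator = match.arg(si_denominator),
      sleep_bridge = match.arg(sleep_bridge),
      rng_seed = rng_seed
    ),
    class = "study_config"
  )
}

#' Read a study configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [study_config()]; `sleep_policy`
#' is a nested mapping with keys `policy`, `min_hours`, `night_start`,
#' `night_end`. Keys absent from the file keep their defaults; arguments
#' supplied through `...` override file values.
#'
#' @param path path to a YAML file.
#' @param ... overrides passed on to [study_config()].
#' @return a `study_config` list.
#' @export
read_study_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sleep_policy)) {
    raw$sleep_policy <- do.call(sleep_policy, raw$sleep_policy)
  }
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(study_config, raw)
}
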