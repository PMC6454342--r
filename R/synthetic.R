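#' Specification of a synthetic smartphone-use cohort
#'
#' Defines the generating conditions for [generate_cohort()]. Defaults are
#' calibrated to the published descriptive statistics of a 33-participant,
#' 8-week passively sensed cohort (see [reference_cohort_stats()]): about
#' 57 use episodes per day averaging about 5.7 h of daily use, roughly 40%
#' of episodes proactive but only about 23% of use time (proactive
#' episodes are shorter), a nightly sleep window, a weekday/weekend cycle,
#' and a slow multiplicative random-walk drift of the episode rate across
#' weeks that makes between-period correlations decay with the time
#' interval separating them.
#'
#' Between-user traits: episode rate and mean episode duration are
#' log-normal (moment-matched to the given mean/SD); the proactive
#' probability and the weekend multiplier are clipped normals; the
#' proactive/overall duration ratio is log-normal around
#' `proactive_duration_ratio_mean`. An `addiction_latent` standard-normal
#' trait is tied to the user's proactive-use-duration propensity by a
#' Gaussian copula with correlation `latent_target_r`, and is discretized
#' into SPAI-5 totals by an affine map to mean `spai5_mean`, SD
#' `spai5_sd`, rounded and clipped to 5--20.
#'
#' @param n_users number of users (default 33).
#' @param n_weeks weeks of data per user (default 8).
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @param episode_rate_mean,episode_rate_sd between-user mean/SD of daily
#'   episode count.
#' @param mean_episode_duration_mean,mean_episode_duration_sd between-user
#'   mean/SD (s) of the user's mean episode duration.
#' @param episode_duration_sigma within-user log-normal sigma of episode
#'   durations (right-skewed session lengths).
#' @param proactive_prob_mean,proactive_prob_sd between-user mean/SD of
#'   the probability that an episode is proactive (clipped to 0.02--0.95).
#' @param proactive_duration_ratio_mean,proactive_duration_ratio_sigma
#'   mean and log-normal sigma of the ratio of proactive to overall mean
#'   episode duration (< 1: proactive episodes are shorter).
#' @param sleep_start_mean,sleep_start_sd,sleep_end_mean,sleep_end_sd
#'   clock hours of the nightly no-use window (start clipped to
#'   21.5--23.9, end to 5.5--9.5, so the window spans midnight).
#' @param weekend_multiplier_mean,weekend_multiplier_sd between-user
#'   weekend/weekday rate contrast (clipped to 0.6--1.8); the weekly
#'   pattern is normalized to mean 1 so it does not bias daily means.
#' @param drift_sd_per_week SD of the weekly increments of the
#'   multiplicative (log-scale) random walk on the episode rate; 0 gives
#'   perfectly stable traits.
#' @param latent_target_r copula correlation between `addiction_latent`
#'   and the (log) proactive-use-duration propensity.
#' @param spai5_mean,spai5_sd target mean/SD of SPAI-5 totals.
#' @param start_date first simulated calendar day (a Monday keeps week
#'   indices aligned with the weekday/weekend cycle).
#' @param proactive_window seconds before screen-on within which reactive
#'   notifications are placed (match the classifier window).
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_users = 33,
                        n_weeks = 8,
                        seed = 1L,
                        episode_rate_mean = 57.29,
                        episode_rate_sd = 22.96,
                        mean_episode_duration_mean = 360.7,
                        mean_episode_duration_sd = 180,
                        episode_duration_sigma = 1.0,
                        proactive_prob_mean = 0.401,
                        proactive_prob_sd = 0.14,
                        proactive_duration_ratio_mean = 0.58,
                        proactive_duration_ratio_sigma = 0.45,
                        sleep_start_mean = 23.2, sleep_start_sd = 0.6,
                        sleep_end_mean = 7.5, sleep_end_sd = 0.75,
                        weekend_multiplier_mean = 1.1, weekend_multiplier_sd = 0.15,
                        drift_sd_per_week = 0.05,
                        latent_target_r = 0.4,
                        spai5_mean = 12.55, spai5_sd = 2.41,
                        start_date = as.Date("2017-03-06"),
                        proactive_window = 60) {
  spec <- as.list(environment())
  sds <- c("episode_rate_sd", "mean_episode_duration_sd", "proactive_prob_sd",
           "sleep_start_sd", "sleep_end_sd", "weekend_multiplier_sd", "spai5_sd")
  if (any(!vapply(spec[sds], function(x) is.finite(x) && x > 0, logical(1)))) {
    stop("trait SDs must be positive and finite", call. = FALSE)
  }
  stopifnot(
    n_users >= 2, n_weeks >= 1,
    drift_sd_per_week >= 0,
    latent_target_r >= -1, latent_target_r <= 1,
    episode_rate_mean > 0, mean_episode_duration_mean > 0,
    proactive_prob_mean >= 0, proactive_prob_mean <= 1
  )
  structure(spec, class = "cohort_spec")
}

# lognormal parameters matched to a target mean and sd
lnorm_match <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Sample per-user traits for a synthetic cohort
#'
#' Draws the between-user traits described in [cohort_spec()], including
#' the addiction latent tied by a Gaussian copula to the standardized log
#' proactive-use-duration propensity (the product of episode rate,
#' proactive probability, mean episode duration and proactive-duration
#' ratio). Uses the current RNG state; [generate_cohort()] seeds it from
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return tibble of one row per user: `user_id`, `base_episode_rate`,
#'   `base_mean_episode_duration`, `proactive_prob`,
#'   `proactive_duration_ratio`, `sleep_start`, `sleep_end` (clock
#'   hours), `weekend_multiplier`, `addiction_latent`.
#' @export
sample_traits <- function(spec) {
  n <- spec$n_users
  lr <- lnorm_match(spec$episode_rate_mean, spec$episode_rate_sd)
  ld <- lnorm_match(spec$mean_episode_duration_mean, spec$mean_episode_duration_sd)

  rate <- rlnorm(n, lr$meanlog, lr$sdlog)
  mean_dur <- rlnorm(n, ld$meanlog, ld$sdlog)
  p <- pmin(pmax(rnorm(n, spec$proactive_prob_mean, spec$proactive_prob_sd),
                 0.02), 0.95)
  sig <- spec$proactive_duration_ratio_sigma
  ratio <- spec$proactive_duration_ratio_mean * exp(rnorm(n, 0, sig) - sig^2 / 2)
  ratio <- pmin(pmax(ratio, 0.1), 0.9 / p, 1.5)
  sleep_start <- pmin(pmax(rnorm(n, spec$sleep_start_mean, spec$sleep_start_sd),
                           21.5), 23.9)
  sleep_end <- pmin(pmax(rnorm(n, spec$sleep_end_mean, spec$sleep_end_sd),
                         5.5), 9.5)
  wm <- pmin(pmax(rnorm(n, spec$weekend_multiplier_mean, spec$weekend_multiplier_sd),
                  0.6), 1.8)

  # Gaussian copula: the latent shares correlation latent_target_r with
  # the standardized log expected daily proactive duration
  pd_prop <- log(rate) + log(p) + log(mean_dur) + log(ratio)
  z <- if (sd(pd_prop) > 0) as.numeric(scale(pd_prop)) else rep(0, n)
  rho <- spec$latent_target_r
  latent <- rho * z + sqrt(1 - rho^2) * rnorm(n)

  tibble::tibble(
    user_id = sprintf("u%03d", seq_len(n)),
    base_episode_rate = rate,
    base_mean_episode_duration = mean_dur,
    proactive_prob = p,
    proactive_duration_ratio = ratio,
    sleep_start = sleep_start,
    sleep_end = sleep_end,
    weekend_multiplier = wm,
    addiction_latent = latent
  )
}

round_ms <- function(x) round(x * 1000) / 1000

#' Generate one user's screen-event stream
#'
#' Simulates `spec$n_weeks * 7` days. Each day has a protected sleep
#' window (no use); the waking span holds a Poisson number of use
#' episodes (mean = episode rate x normalized weekday/weekend factor x
#' the week's drift factor) with log-normal durations, separated by
#' random gaps (at least 1 s) that fill the remaining waking time.
#' Episodes are independently proactive with the user's probability;
#' proactive episodes get a shorter mean duration by the user's
#' proactive-duration ratio (reactive episodes are lengthened to keep the
#' overall mean). Each reactive episode gets exactly one notification
#' placed strictly inside the window before its screen-on — and strictly
#' outside every proactive episode's window — so the downstream
#' classifier's labels equal the generator's by construction. Days whose
#' sampled durations cannot fit the waking span are re-drawn (up to 100
#' attempts, then scaled down with a warning).
#'
#' @param traits a one-row tibble from [sample_traits()].
#' @param spec a [cohort_spec()].
#' @return list with `events` (tibble `user_id`, `timestamp`,
#'   `event_type`) and `episodes` (the generating truth: `user_id`,
#'   `date`, `start`, `end`, `duration`, `proactive`).
#' @export
generate_user_events <- function(traits, spec) {
  n_days <- spec$n_weeks * 7L
  day0 <- as.numeric(as.POSIXct(paste(spec$start_date), tz = "UTC"))

  drift <- exp(cumsum(c(0, rnorm(spec$n_weeks - 1, 0, spec$drift_sd_per_week))))
  d <- seq_len(n_days)
  week <- (d - 1L) %/% 7L + 1L
  weekend <- ((d - 1L) %% 7L) >= 5L   # start_date is a Monday
  wk_norm <- 7 / (5 + 2 * traits$weekend_multiplier)
  day_mult <- ifelse(weekend, traits$weekend_multiplier * wk_norm, wk_norm)
  lambda <- traits$base_episode_rate * day_mult * drift[week]
  n_ep <- rpois(n_days, lambda)

  wake_start <- traits$sleep_end * 3600
  wake_end <- traits$sleep_start * 3600
  span <- wake_end - wake_start

  day_id <- rep.int(d, n_ep)
  total <- sum(n_ep)
  if (total == 0) {
    return(list(events = empty_events(), episodes = empty_truth()))
  }
  pro <- runif(total) < traits$proactive_prob
  r <- traits$proactive_duration_ratio
  p <- traits$proactive_prob
  mult <- ifelse(pro, r, (1 - p * r) / (1 - p))
  meanlog <- log(traits$base_mean_episode_duration * mult) -
    spec$episode_duration_sigma^2 / 2
  dur <- pmax(rlnorm(total, meanlog, spec$episode_duration_sigma), 1)

  # re-draw days whose episodes (plus 1-s minimum gaps) overflow waking time
  for (attempt in seq_len(100)) {
    day_sum <- rowsum(dur, day_id, reorder = FALSE)
    need <- day_sum + (rowsum(rep(1, total), day_id, reorder = FALSE) + 1)
    bad_days <- as.integer(rownames(day_sum))[need[, 1] > span]
    if (length(bad_days) == 0) break
    i <- day_id %in% bad_days
    dur[i] <- pmax(rlnorm(sum(i), meanlog[i], spec$episode_duration_sigma), 1)
  }
  day_sum <- rowsum(dur, day_id, reorder = FALSE)[, 1]
  n_day <- rowsum(rep(1, total), day_id, reorder = FALSE)[, 1]
  over <- day_sum + n_day + 1 > span
  if (any(over)) {
    warning("scaling down durations on ", sum(over),
            " overfull day(s) after 100 re-draws", call. = FALSE)
    days_over <- as.integer(names(day_sum))[over]
    i <- day_id %in% days_over
    f <- (span - n_day - 1)[match(day_id[i], as.integer(names(day_sum)))] /
      day_sum[match(day_id[i], as.integer(names(day_sum)))]
    dur[i] <- dur[i] * f
    day_sum <- rowsum(dur, day_id, reorder = FALSE)[, 1]
  }

  # gaps: N+1 per day, each >= 1 s, Dirichlet-distributed remainder
  gap_day <- rep.int(as.integer(names(day_sum)), n_day + 1)
  g <- rexp(length(gap_day))
  g_tot <- rowsum(g, gap_day, reorder = FALSE)[, 1]
  free <- (span - day_sum - (n_day + 1))[match(gap_day, as.integer(names(day_sum)))]
  gaps <- 1 + g / g_tot[match(gap_day, as.integer(names(g_tot)))] * free

  # interleave: start_i = wake_start + sum(gaps[1..i]) + sum(dur[1..i-1])
  new_gap_day <- c(TRUE, gap_day[-1] != gap_day[-length(gap_day)])
  gsum <- gcumsum(gaps, new_gap_day)
  gap_rank <- gseq(new_gap_day)
  pre_gap_cum <- gsum[gap_rank <= n_day[match(gap_day, as.integer(names(day_sum)))]]
  new_ep_day <- c(TRUE, day_id[-1] != day_id[-total])
  dsum <- gcumsum(dur, new_ep_day)
  start_off <- wake_start + pre_gap_cum + dsum - dur
  s <- round_ms(day0 + (day_id - 1) * 86400 + start_off)
  e <- round_ms(s + dur)

  # Reactive notifications must fall inside their own episode's pre-onset
  # window but inside no proactive episode's window. It suffices to stay
  # clear of the two *nearest* proactive neighbours (earlier proactive
  # windows end even earlier; later ones start even later). When episodes
  # are so crammed that no such instant exists, the episode is relabelled
  # proactive; relabelling is monotone, so iterating reaches a fixpoint.
  w <- spec$proactive_window
  n_all <- length(s)
  repeat {
    prev_pro <- c(-Inf, cummax(ifelse(pro, s, -Inf))[-n_all])
    next_pro <- c(rev(cummin(rev(ifelse(pro, s, Inf))))[-1], Inf)
    lo <- pmax(s - w, prev_pro)
    hi <- pmin(s, next_pro - w)
    infeasible <- !pro & (hi - lo < 0.01)
    if (!any(infeasible)) break
    pro[infeasible] <- TRUE
  }
  ri <- which(!pro)
  tn <- round_ms(lo[ri] + 0.002 + runif(length(ri)) * (hi[ri] - lo[ri] - 0.004))
  tn <- pmin(pmax(tn, lo[ri] + 0.001), hi[ri] - 0.001)

  uid <- traits$user_id
  ev <- tibble::tibble(
    user_id = uid,
    t = c(s, e, tn),
    event_type = c(rep("screen_on", total), rep("screen_off", total),
                   rep("notification", length(tn)))
  )
  ev <- ev[order(ev$t, method = "radix"), ]
  events <- tibble::tibble(
    user_id = ev$user_id,
    timestamp = as.POSIXct(ev$t, origin = "1970-01-01", tz = "UTC"),
    event_type = ev$event_type
  )
  truth <- tibble::tibble(
    user_id = uid,
    date = spec$start_date + day_id - 1L,
    start = as.POSIXct(s, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(e, origin = "1970-01-01", tz = "UTC"),
    duration = e - s,
    proactive = pro
  )
  list(events = events, episodes = truth)
}

empty_events <- function() {
  tibble::tibble(user_id = character(),
                 timestamp = as.POSIXct(character(), tz = "UTC"),
                 event_type = character())
}

empty_truth <- function() {
  tibble::tibble(user_id = character(), date = as.Date(character()),
                 start = as.POSIXct(character(), tz = "UTC"),
                 end = as.POSIXct(character(), tz = "UTC"),
                 duration = numeric(), proactive = logical())
}

#' Generate a full synthetic cohort
#'
#' Seeds the RNG from `spec$seed`, samples traits, simulates every user's
#' event stream, and scores SPAI-5 questionnaires from the addiction
#' latent. The result is fully reproducible from the seed; with `out_dir`
#' set, `events.csv` and `spai5.csv` are written in the formats of
#' [read_screen_events()] and [read_spai5()].
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory to write `events.csv` and
#'   `spai5.csv` into (created if needed).
#' @return list of class `screen_cohort`: `events`, `spai5`, `traits`,
#'   `episodes` (generating-truth episodes incl. proactive labels), and
#'   `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), out_dir = NULL) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  traits <- sample_traits(spec)
  sims <- purrr::map(seq_len(spec$n_users),
                     function(i) generate_user_events(traits[i, ], spec))
  events <- dplyr::bind_rows(purrr::map(sims, "events"))
  episodes <- dplyr::bind_rows(purrr::map(sims, "episodes"))

  total <- as.integer(pmin(pmax(round(spec$spai5_mean +
                                        spec$spai5_sd * traits$addiction_latent),
                                5), 20))
  base <- total %/% 5L
  rem <- total %% 5L
  items <- t(vapply(seq_along(total),
                    function(i) base[i] + as.integer(seq_len(5) <= rem[i]),
                    integer(5)))
  spai5 <- tibble::tibble(user_id = traits$user_id)
  for (j in 1:5) spai5[[paste0("item", j)]] <- items[, j]
  spai5$total <- total

  out <- structure(
    list(events = events, spai5 = spai5, traits = traits,
         episodes = episodes, spec = spec),
    class = "screen_cohort"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_screen_events(events, file.path(out_dir, "events.csv"))
    write_spai5(spai5, file.path(out_dir, "spai5.csv"))
  }
  out
}

#' @export
print.screen_cohort <- function(x, ...) {
  cat(sprintf(
    "<screen_cohort> %d users x %d weeks: %d events, %d use episodes\n",
    x$spec$n_users, x$spec$n_weeks, nrow(x$events), nrow(x$episodes)
  ))
  invisible(x)
}

#' Published descriptive statistics of the reference cohort
#'
#' Means and SDs of the seven daily use parameters (averaged per user over
#' two months) and the SPAI-5 total, as printed for the original
#' 33-participant cohort. Used to calibrate [cohort_spec()] defaults and
#' as the input for the printed-ratio checks in [use_profile_ratios()].
#'
#' @return tibble `parameter`, `mean`, `sd`.
#' @export
reference_cohort_stats <- function() {
  tibble::tibble(
    parameter = c(PARAM_NAMES, "SPAI5"),
    mean = c(57.29, 20666.96, 22.97, 4806.66, 3070.41, 1417.35, 1949.38, 12.55),
    sd = c(22.96, 12702.38, 14.11, 10279.38, 1421.50, 853.55, 1492.87, 2.41)
  )
}

#' Cohort-level descriptive statistics of daily parameters
#'
#' Per-user period means (via [summarize_period()]) reduced to a
#' cohort-level mean and SD per parameter — the same shape as
#' [reference_cohort_stats()].
#'
#' @param daily daily-parameter tibble.
#' @return tibble `parameter`, `mean`, `sd`, `n_users`.
#' @export
cohort_descriptives <- function(daily) {
  per_user <- summarize_period(daily)
  names(per_user)[names(per_user) == "mean"] <- "user_mean"
  out <- dplyr::summarise(
    dplyr::group_by(per_user, .data$parameter),
    mean = mean(.data$user_mean, na.rm = TRUE),
    sd = sd(.data$user_mean, na.rm = TRUE),
    n_users = sum(!is.na(.data$user_mean)),
    .groups = "drop"
  )
  out$parameter <- as.character(out$parameter)
  out
}

#' Headline ratios of a use profile
#'
#' From a `parameter`/`mean` table (either [reference_cohort_stats()] or
#' [cohort_descriptives()] output): the proactive share of use frequency
#' and of use duration (percent), and the mean daily use duration in
#' hours.
#'
#' @param stats tibble with columns `parameter` and `mean` covering `F`,
#'   `D`, `PF`, `PD`.
#' @return one-row tibble `proactive_frequency_pct`,
#'   `proactive_duration_pct`, `mean_daily_hours`.
#' @export
use_profile_ratios <- function(stats) {
  m <- setNames(stats$mean, stats$parameter)
  tibble::tibble(
    proactive_frequency_pct = 100 * m[["PF"]] / m[["F"]],
    proactive_duration_pct = 100 * m[["PD"]] / m[["D"]],
    mean_daily_hours = m[["D"]] / 3600
  )
}
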