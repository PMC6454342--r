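#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation via [stats::cor.test()]. Pairs with a
#' missing value are dropped. With fewer than 3 complete pairs, or zero
#' variance in either vector, the correlation is undefined and reported as
#' `NA` — never coerced to 0 or 1.
#'
#' @param x,y numeric vectors of equal length.
#' @return one-row tibble `r`, `p`, `n` (complete pairs used).
#' @export
#' @examples
#' pearson_test(1:5, 2 * (1:5) + 1) # r = 1
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
}

# per-user, per-parameter means over a set of study weeks, as a wide-ish
# long tibble (user_id, parameter, mean); `weekly` is daily params + week
block_means <- function(weekly, weeks) {
  sub <- weekly[weekly$week %in% weeks, ]
  long <- tidyr::pivot_longer(sub[c("user_id", PARAM_NAMES)],
                              dplyr::all_of(PARAM_NAMES),
                              names_to = "parameter", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$user_id, .data$parameter),
    mean = if (any(!is.na(.data$value))) mean(.data$value, na.rm = TRUE) else NA_real_,
    .groups = "drop"
  )
}

check_record_length <- function(weekly, total_weeks) {
  len <- dplyr::summarise(dplyr::group_by(weekly, .data$user_id),
                          weeks = max(.data$week))
  short <- len$user_id[len$weeks < total_weeks]
  if (length(short) > 0) {
    warning("excluding ", length(short),
            " user(s) with fewer than ", total_weeks, " weeks of data",
            call. = FALSE)
  }
  weekly[!(weekly$user_id %in% short), ]
}

#' Fundamental time unit: block means vs the full-record mean
#'
#' How representative is a 1-, 2- or 4-week block of a user's typical
#' 2-month (8-week) use? For each parameter and each grid-aligned,
#' non-overlapping block of `unit_weeks` weeks (weeks 1, 2, ..;
#' pairs 1-2, 3-4, ..; halves 1-4, 5-8), the per-user block mean is
#' correlated across users with the per-user mean over the whole
#' `total_weeks` record. The block is part of the whole, as in the
#' original analysis; `leave_block_out = TRUE` instead correlates against
#' the mean of the *other* weeks. Correlations at or above `threshold`
#' are flagged "high".
#'
#' @param daily daily-parameter tibble from [daily_parameters()].
#' @param unit_weeks block length in weeks (divisor of `total_weeks`).
#' @param total_weeks length of the reference record (default 8, i.e. two
#'   months).
#' @param threshold "high correlation" criterion (default 0.75).
#' @param leave_block_out exclude the block from the reference mean.
#' @return a `unit_stability` tibble: `parameter`, `unit_weeks`, `block`,
#'   `weeks`, `r`, `p`, `n_users`, `high`.
#' @export
unit_vs_total <- function(daily, unit_weeks, total_weeks = 8,
                          threshold = 0.75, leave_block_out = FALSE) {
  stopifnot(unit_weeks >= 1, total_weeks %% unit_weeks == 0)
  weekly <- add_week(daily)
  weekly <- check_record_length(weekly, total_weeks)
  n_blocks <- total_weeks %/% unit_weeks
  total <- block_means(weekly, seq_len(total_weeks))

  res <- purrr::map_dfr(seq_len(n_blocks), function(b) {
    wk <- ((b - 1) * unit_weeks + 1):(b * unit_weeks)
    ref <- if (leave_block_out) {
      block_means(weekly, setdiff(seq_len(total_weeks), wk))
    } else {
      total
    }
    bm <- dplyr::inner_join(block_means(weekly, wk), ref,
                            by = c("user_id", "parameter"),
                            suffix = c("_block", "_total"))
    out <- dplyr::reframe(
      dplyr::group_by(bm, .data$parameter),
      pearson_test(.data$mean_block, .data$mean_total)
    )
    out$block <- b
    out$weeks <- paste(range(wk), collapse = "-")
    out
  })
  res$unit_weeks <- unit_weeks
  res$high <- res$r >= threshold
  res$n_users <- res$n
  res$parameter <- factor(res$parameter, levels = PARAM_NAMES)
  res <- dplyr::arrange(
    res[c("parameter", "unit_weeks", "block", "weeks", "r", "p", "n_users", "high")],
    .data$parameter, .data$block
  )
  structure(res, class = c("unit_stability", class(res)),
            threshold = threshold, total_weeks = total_weeks)
}

#' Independent cycle: correlation of two use periods by time interval
#'
#' How long does a use pattern persist? Two blocks of `unit_weeks` weeks
#' separated by a gap of `TI` weeks are correlated across users (per-user
#' block means of each parameter), for every ordered pair of
#' non-overlapping blocks at weekly offsets with that exact gap; the pair
#' correlations are averaged into a single temporal-reliability index per
#' `TI`. For 1-week blocks in an 8-week record, `TI` runs 0..6 with
#' 7, 6, .., 1 contributing pairs (TI = 0 averages week 1 vs 2, .., week
#' 7 vs 8; TI = 6 is the single pair week 1 vs week 8).
#'
#' @param daily daily-parameter tibble.
#' @param unit_weeks period length in weeks (the original analysis used 1
#'   and 2).
#' @param max_weeks record length in weeks (default 8).
#' @param ti optional integer vector restricting the reported time
#'   intervals (e.g. `c(0, 2, 4)` for grid-aligned 2-week periods).
#' @return a `cycle_stability` tibble: `parameter`, `unit_weeks`, `TI`,
#'   `mean_r`, `n_pairs`; the per-pair correlations are in attribute
#'   `pairs`.
#' @export
independent_cycle <- function(daily, unit_weeks, max_weeks = 8, ti = NULL) {
  stopifnot(unit_weeks >= 1, max_weeks >= 2 * unit_weeks)
  weekly <- add_week(daily)
  weekly <- check_record_length(weekly, max_weeks)
  starts <- seq_len(max_weeks - unit_weeks + 1)
  bm <- purrr::map(starts, function(s) {
    block_means(weekly, s:(s + unit_weeks - 1))
  })

  pairs <- tidyr::expand_grid(s1 = starts, s2 = starts)
  pairs <- pairs[pairs$s2 >= pairs$s1 + unit_weeks, ]
  pairs$TI <- pairs$s2 - pairs$s1 - unit_weeks
  if (!is.null(ti)) pairs <- pairs[pairs$TI %in% ti, ]

  detail <- purrr::pmap_dfr(pairs, function(s1, s2, TI) {
    m <- dplyr::inner_join(bm[[s1]], bm[[s2]],
                           by = c("user_id", "parameter"),
                           suffix = c("_1", "_2"))
    out <- dplyr::reframe(
      dplyr::group_by(m, .data$parameter),
      pearson_test(.data$mean_1, .data$mean_2)
    )
    out$s1 <- s1; out$s2 <- s2; out$TI <- TI
    out
  })
  res <- dplyr::summarise(
    dplyr::group_by(detail, .data$parameter, .data$TI),
    mean_r = mean(.data$r, na.rm = TRUE),
    n_pairs = dplyr::n(),
    .groups = "drop"
  )
  res$unit_weeks <- unit_weeks
  res$parameter <- factor(res$parameter, levels = PARAM_NAMES)
  res <- dplyr::arrange(res[c("parameter", "unit_weeks", "TI", "mean_r", "n_pairs")],
                        .data$parameter, .data$TI)
  structure(res, class = c("cycle_stability", class(res)), pairs = detail)
}

#' Correlate two-month use parameters with SPAI-5 addiction scores
#'
#' For each of the seven parameters, the Pearson correlation across users
#' between the per-user period mean and the SPAI-5 total score. Users
#' present in only one of the two tables are dropped (and counted in
#' attribute `n_unmatched`). p-values are unadjusted, as in the original
#' exploratory analysis.
#'
#' @param period_summary long summary from [summarize_period()].
#' @param spai5 tibble from [read_spai5()] (needs `user_id`, `total`).
#' @return tibble `parameter`, `r`, `p`, `n_users`.
#' @export
addiction_correlations <- function(period_summary, spai5) {
  merged <- dplyr::inner_join(period_summary, spai5[c("user_id", "total")],
                              by = "user_id")
  n_unmatched <- length(setdiff(
    union(unique(period_summary$user_id), unique(spai5$user_id)),
    unique(merged$user_id)
  ))
  res <- dplyr::reframe(
    dplyr::group_by(merged, .data$parameter),
    pearson_test(.data$mean, .data$total)
  )
  names(res)[names(res) == "n"] <- "n_users"
  res$parameter <- factor(res$parameter, levels = PARAM_NAMES)
  res <- dplyr::arrange(res, .data$parameter)
  attr(res, "n_unmatched") <- n_unmatched
  res
}

#' Pairwise intercorrelations of the seven use parameters
#'
#' Pearson correlations across users between the period means of every
#' pair of parameters (the structure of a descriptive correlation table).
#'
#' @param period_summary long summary from [summarize_period()].
#' @return tibble `parameter_1`, `parameter_2`, `r`, `p`, `n_users` for
#'   the lower triangle.
#' @export
parameter_intercorrelations <- function(period_summary) {
  wide <- tidyr::pivot_wider(period_summary[c("user_id", "parameter", "mean")],
                             names_from = "parameter", values_from = "mean")
  combos <- utils::combn(PARAM_NAMES, 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(i) {
    p1 <- combos[1, i]; p2 <- combos[2, i]
    out <- pearson_test(wide[[p1]], wide[[p2]])
    names(out)[names(out) == "n"] <- "n_users"
    dplyr::bind_cols(tibble::tibble(parameter_1 = p1, parameter_2 = p2), out)
  })
}

# ---- broom-style and plotting methods -------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy stability results
#'
#' @param x a `unit_stability` or `cycle_stability` object.
#' @param ... unused.
#' @return a plain tibble of the result rows.
#' @method tidy unit_stability
#' @export
tidy.unit_stability <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  attr(out, "threshold") <- NULL
  attr(out, "total_weeks") <- NULL
  out
}

#' @rdname tidy.unit_stability
#' @method tidy cycle_stability
#' @export
tidy.cycle_stability <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  attr(out, "pairs") <- NULL
  out
}

#' One-row summaries of stability results
#'
#' For `unit_stability`: the number of correlations, how many meet the
#' "high" criterion, and the weakest one. For `cycle_stability`: the
#' range of the temporal-reliability index over time intervals.
#'
#' @param x a `unit_stability` or `cycle_stability` object.
#' @param ... unused.
#' @return a one-row tibble.
#' @method glance unit_stability
#' @export
glance.unit_stability <- function(x, ...) {
  tibble::tibble(
    unit_weeks = x$unit_weeks[1],
    threshold = attr(x, "threshold"),
    n_correlations = nrow(x),
    n_high = sum(x$high, na.rm = TRUE),
    prop_high = mean(x$high, na.rm = TRUE),
    min_r = suppressWarnings(min(x$r, na.rm = TRUE))
  )
}

#' @rdname glance.unit_stability
#' @method glance cycle_stability
#' @export
glance.cycle_stability <- function(x, ...) {
  tibble::tibble(
    unit_weeks = x$unit_weeks[1],
    n_ti = length(unique(x$TI)),
    mean_r_ti0 = mean(x$mean_r[x$TI == 0]),
    mean_r_max_ti = mean(x$mean_r[x$TI == max(x$TI)]),
    min_mean_r = min(x$mean_r, na.rm = TRUE)
  )
}

#' Plot stability results
#'
#' `unit_stability`: per-parameter correlation with the full-record mean
#' for each block, with the "high correlation" criterion as a dashed
#' line. `cycle_stability`: the averaged correlation of two independent
#' periods against the time interval separating them.
#'
#' @param object a stability result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot unit_stability
#' @export
autoplot.unit_stability <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$weeks, y = .data$r,
                               colour = .data$parameter, group = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"), linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("%d-week block", object$unit_weeks[1]),
      y = sprintf("r with %d-week mean", attr(object, "total_weeks")),
      colour = "parameter"
    ) +
    ggplot2::ylim(min(0, min(object$r, na.rm = TRUE)), 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.unit_stability
#' @method autoplot cycle_stability
#' @export
autoplot.cycle_stability <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$TI, y = .data$mean_r,
                               colour = .data$parameter, group = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "time interval between periods (weeks)",
      y = sprintf("mean r across %d-week period pairs", object$unit_weeks[1]),
      colour = "parameter"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
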