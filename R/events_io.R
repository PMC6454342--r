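#' Read a screen-event log
#'
#' Reads a tidy event log with columns `user_id`, `timestamp`, `event_type`
#' from CSV or JSON-lines. Timestamps must be ISO 8601 with an explicit UTC
#' offset (e.g. `2017-03-02T21:15:04+08:00`); fractional seconds are
#' accepted. `event_type` must be one of `screen_on`, `screen_off`,
#' `notification`. Rows with an unparseable timestamp or an unknown event
#' type are rejected individually (never silently): they are counted and
#' returned in the `rejections` attribute with their line number and
#' reason. A missing column is a hard error.
#'
#' Events are returned sorted by user and timestamp; rows with identical
#' timestamps keep their input order (stable sort), so identical input
#' bytes always yield the identical stream.
#'
#' @param path path to the log file.
#' @param format `"csv"` or `"jsonl"`; guessed from the file extension by
#'   default.
#' @return a tibble with columns `user_id` (character), `timestamp`
#'   (POSIXct, UTC), `event_type` (character), carrying attributes
#'   `rejections` (tibble of `line`, `reason`) and `n_rejected`.
#' @seealso [write_screen_events()], [pair_screen_events()]
#' @export
read_screen_events <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json", path)) "jsonl" else "csv"
  }
  if (format == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
    line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    raw <- purrr::map_dfr(lines, function(l) {
      rec <- jsonlite::fromJSON(l)
      tibble::as_tibble(lapply(rec, as.character))
    })
    line_no <- seq_len(nrow(raw))
  }
  needed <- c("user_id", "timestamp", "event_type")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("event log is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    out <- tibble::tibble(
      user_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
      event_type = character()
    )
    attr(out, "rejections") <- tibble::tibble(line = integer(), reason = character())
    attr(out, "n_rejected") <- 0L
    return(out)
  }

  ts <- suppressWarnings(
    readr::parse_datetime(raw$timestamp, format = "", locale = readr::locale(tz = "UTC"))
  )
  bad_ts <- is.na(ts)
  bad_type <- !(raw$event_type %in% EVENT_TYPES)
  rejections <- dplyr::bind_rows(
    tibble::tibble(line = line_no[bad_ts], reason = "unparseable timestamp"),
    tibble::tibble(line = line_no[bad_type & !bad_ts],
                   reason = paste0("unknown event_type '", raw$event_type[bad_type & !bad_ts], "'"))
  )
  keep <- !bad_ts & !bad_type
  out <- tibble::tibble(
    user_id = raw$user_id[keep],
    timestamp = ts[keep],
    event_type = raw$event_type[keep]
  )
  # stable sort: order() with a single tie-breaking key that is the input row
  out <- out[order(out$user_id, out$timestamp, method = "radix"), ]
  attr(out, "rejections") <- rejections
  attr(out, "n_rejected") <- nrow(rejections)
  out
}

#' Write a screen-event log
#'
#' Inverse of [read_screen_events()]; timestamps are written as ISO 8601
#' UTC with millisecond resolution (`+00:00` offset), which round-trips
#' through the reader.
#'
#' @param events tibble with `user_id`, `timestamp`, `event_type`.
#' @param path output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_screen_events <- function(events, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  out <- tibble::tibble(
    user_id = events$user_id,
    timestamp = format_iso8601(events$timestamp),
    event_type = events$event_type
  )
  if (format == "csv") {
    readr::write_csv(out, path)
  } else {
    writeLines(vapply(seq_len(nrow(out)), function(i) {
      jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE)
    }, character(1)), path)
  }
  invisible(path)
}

format_iso8601 <- function(t) {
  # %OS3 keeps millisecond resolution; trailing ".000" is harmless
  paste0(format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"), "+00:00")
}

#' Read SPAI-5 questionnaire responses
#'
#' Reads a CSV with columns `user_id`, `item1` ... `item5`, each item an
#' integer Likert score in 1--4 (1 = strongly disagree, 4 = strongly
#' agree). The total score (range 5--20) is computed as the item sum.
#' Users with any item outside 1--4 (or missing) are rejected with a
#' reason; a duplicated `user_id` is a hard error.
#'
#' @param path path to the CSV.
#' @return tibble `user_id`, `item1`..`item5`, `total`, with attributes
#'   `rejections` (tibble of `user_id`, `reason`) and `n_rejected`.
#' @export
read_spai5 <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    user_id = readr::col_character(), .default = readr::col_double()
  ))
  items <- paste0("item", 1:5)
  missing_cols <- setdiff(c("user_id", items), names(raw))
  if (length(missing_cols) > 0) {
    stop("SPAI-5 table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$user_id)) {
    stop("duplicate user_id in SPAI-5 table: ",
         paste(unique(raw$user_id[duplicated(raw$user_id)]), collapse = ", "),
         call. = FALSE)
  }
  item_mat <- as.matrix(raw[items])
  bad <- apply(item_mat, 1, function(x) {
    any(is.na(x)) || any(x < 1 | x > 4) || any(x != round(x))
  })
  rejections <- tibble::tibble(
    user_id = raw$user_id[bad],
    reason = "item outside 1-4 Likert range"
  )
  out <- raw[!bad, c("user_id", items)]
  out$total <- as.integer(rowSums(out[items]))
  attr(out, "rejections") <- rejections
  attr(out, "n_rejected") <- nrow(rejections)
  out
}

#' Write SPAI-5 responses
#'
#' @param spai5 tibble with `user_id` and `item1`..`item5` (a `total`
#'   column, if present, is not written; it is recomputed on read).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spai5 <- function(spai5, path) {
  readr::write_csv(spai5[c("user_id", paste0("item", 1:5))], path)
  invisible(path)
}

#' Write and read daily parameter tables
#'
#' One row per user-day with columns `user_id`, `date`, `F`, `D`, `PF`,
#' `PD`, `RMSSD`, `SI`, `CI` (durations in seconds). Undefined reciprocity
#' statistics (days with too few episodes) are written as empty cells,
#' never as zero, and read back as `NA`.
#'
#' @param daily tibble as produced by [daily_parameters()].
#' @param path file path.
#' @return `write_daily_parameters()` returns `path` invisibly;
#'   `read_daily_parameters()` returns the tibble.
#' @export
write_daily_parameters <- function(daily, path) {
  readr::write_csv(daily[c("user_id", "date", PARAM_NAMES)], path, na = "")
  invisible(path)
}

#' @rdname write_daily_parameters
#' @export
read_daily_parameters <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    user_id = readr::col_character(),
    date = readr::col_date(),
    .default = readr::col_double()
  ))
}
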