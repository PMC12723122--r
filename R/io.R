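#' Read an accrual table from delimited text
#'
#' Two layouts are supported. `"quarterly"` tables are pre-aggregated, with
#' columns `quarter` (or `quarter_index`), `season`, `count` and optionally
#' `duration` and `start_date`; they are returned as an `accrual_series`.
#' `"monthly"` tables have columns `month_start` (ISO 8601 dates) and
#' `count`; they are returned as a tibble of monthly records for
#' [quarterize()]. The delimiter (comma or tab) is sniffed from the header.
#' Validation failures report the offending rows.
#'
#' @param path Path to the delimited file (header required).
#' @param layout `"auto"` (default; decided by the columns present),
#'   `"quarterly"` or `"monthly"`.
#' @param calendar A [season_calendar()] for date/season checks.
#' @param trial_label Optional label attached to a quarterly result.
#' @return An `accrual_series` (quarterly) or a tibble with `month_start`
#'   and `count` (monthly).
#' @export
read_accrual_table <- function(path, layout = c("auto", "quarterly", "monthly"),
                               calendar = season_calendar(), trial_label = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (nrow(tab) == 0) abort(sprintf("No data rows in %s", path))

  if (layout == "auto") {
    layout <- if ("month_start" %in% names(tab)) "monthly" else "quarterly"
  }

  if (layout == "monthly") {
    need <- c("month_start", "count")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0) {
      abort(sprintf("Monthly layout requires column(s): %s", paste(miss, collapse = ", ")))
    }
    month_start <- as.Date(tab$month_start, format = "%Y-%m-%d")
    bad <- which(is.na(month_start))
    if (length(bad) > 0) {
      abort(sprintf("Unparseable `month_start` date(s) in row(s): %s",
                    paste(bad, collapse = ", ")))
    }
    count <- check_count_column(tab$count)
    return(tibble::tibble(month_start = month_start, count = count))
  }

  need <- c("season", "count")
  if (!any(c("quarter", "quarter_index") %in% names(tab)) ||
      !all(need %in% names(tab))) {
    abort("Quarterly layout requires columns quarter (or quarter_index), season, count.")
  }
  qcol <- tab[["quarter"]] %||% tab[["quarter_index"]]
  q <- suppressWarnings(as.integer(qcol))
  if (anyNA(q) || !identical(q, seq_len(nrow(tab)))) {
    abort("`quarter` must be the integers 1..J in order with no gaps.")
  }
  count <- check_count_column(tab$count)
  duration <- if (is.null(tab[["duration"]])) {
    rep(1, nrow(tab))
  } else {
    d <- suppressWarnings(as.numeric(tab$duration))
    bad <- which(is.na(d) | d <= 0 | d > 1)
    if (length(bad) > 0) {
      abort(sprintf("`duration` outside (0, 1] in row(s): %s",
                    paste(bad, collapse = ", ")))
    }
    d
  }
  start_date <- NULL
  if (!is.null(tab[["start_date"]])) {
    start_date <- as.Date(tab$start_date, format = "%Y-%m-%d")
    bad <- which(is.na(start_date))
    if (length(bad) > 0) {
      abort(sprintf("Unparseable `start_date` date(s) in row(s): %s",
                    paste(bad, collapse = ", ")))
    }
  }
  accrual_series(count = count, season = tab$season, duration = duration,
                 start_date = start_date, trial_label = trial_label,
                 calendar = calendar)
}

check_count_column <- function(x) {
  n <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(n) | n < 0 | n != floor(n))
  if (length(bad) > 0) {
    abort(sprintf("`count` must be non-negative integers; bad row(s): %s",
                  paste(bad, collapse = ", ")))
  }
  as.integer(n)
}

#' Write an accrual series (or monthly records) as delimited text
#'
#' Writes the same CSV layout [read_accrual_table()] consumes, so a write
#' followed by a read returns an identical object.
#'
#' @param x An `accrual_series` or a tibble of monthly records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_accrual_table <- function(x, path) {
  if (inherits(x, "accrual_series")) {
    out <- tibble::as_tibble(x)
    out$season <- as.character(out$season)
  } else if (is.data.frame(x) && "month_start" %in% names(x)) {
    out <- tibble::as_tibble(x)[, c("month_start", "count")]
  } else {
    abort("`x` must be an accrual series or a monthly record table.")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
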