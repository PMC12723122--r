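#' Build an accrual series
#'
#' An accrual series is the package's central data structure: an ordered
#' tibble of quarters, one row per quarter, with the number of participants
#' accrued (`count`), the quarter duration as a fraction of a full quarter
#' (`duration`, in (0, 1]) and the season label. It is a tibble, so all the
#' usual dplyr verbs apply; the class carries validation and methods.
#'
#' @param count Integer vector of per-quarter accrual counts (non-negative).
#' @param season Season labels per quarter. If a single label is given it is
#'   taken as the starting season and the rest are continued around the
#'   seasonal cycle.
#' @param duration Quarter durations in (0, 1]; recycled if length 1.
#' @param start_date Optional `Date` vector of quarter start dates. When both
#'   `season` and `start_date` are supplied they must agree under `calendar`.
#' @param trial_label Optional free-text label for the trial.
#' @param excluded_count Participants excluded from modeling (e.g. from a
#'   dropped partial first quarter); carried as an attribute so predictive
#'   totals can still account for them.
#' @param calendar A [season_calendar()] used to check date/season agreement.
#' @return A tibble of class `accrual_series` with columns `quarter`,
#'   `season`, `count`, `duration` (and `start_date` when given).
#' @export
#' @examples
#' accrual_series(count = c(5, 3, 2, 6), season = "summer")
accrual_series <- function(count, season, duration = 1, start_date = NULL,
                           trial_label = NULL, excluded_count = 0L,
                           calendar = season_calendar()) {
  count <- as.numeric(count)
  n <- length(count)
  if (n == 0) abort("An accrual series needs at least one quarter.")
  if (any(is.na(count)) || any(count < 0) || any(count != floor(count))) {
    abort("`count` must be non-negative integers.")
  }
  duration <- rep_len(as.numeric(duration), n)
  if (any(is.na(duration)) || any(duration <= 0) || any(duration > 1)) {
    abort("`duration` must lie in (0, 1].")
  }
  if (length(season) == 1 && n > 1) {
    season <- next_season(season, 0:(n - 1L))
  }
  season <- season_factor(season)
  if (length(season) != n || anyNA(season)) {
    abort("`season` must supply one valid label per quarter (or a single starting label).")
  }
  if (!is.null(start_date)) {
    start_date <- as.Date(start_date)
    if (length(start_date) != n) abort("`start_date` must match the number of quarters.")
    derived <- assign_season(start_date, calendar)
    if (!all(derived == season)) {
      abort("`season` disagrees with the season derived from `start_date`.")
    }
  }
  out <- tibble::tibble(
    quarter = seq_len(n),
    season = season,
    count = as.integer(count),
    duration = duration
  )
  if (!is.null(start_date)) out$start_date <- start_date
  new_accrual_series(out, trial_label = trial_label,
                     excluded_count = as.integer(excluded_count))
}

new_accrual_series <- function(df, trial_label = NULL, excluded_count = 0L) {
  structure(
    df,
    trial_label = trial_label,
    excluded_count = excluded_count,
    class = c("accrual_series", class(tibble::tibble()))
  )
}

#' Coerce a data frame to an accrual series
#'
#' Accepts a data frame with columns `count`, `season` (or `start_date`),
#' and optionally `duration` and `quarter`, validating the accrual-series
#' invariants.
#'
#' @param x A data frame.
#' @inheritParams accrual_series
#' @return An `accrual_series` tibble.
#' @export
as_accrual_series <- function(x, trial_label = NULL, excluded_count = 0L,
                              calendar = season_calendar()) {
  if (inherits(x, "accrual_series")) return(x)
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  if (!"count" %in% names(x)) abort("`x` must have a `count` column.")
  if (!is.null(x[["quarter"]])) {
    if (!identical(as.integer(x$quarter), seq_len(nrow(x)))) {
      abort("`quarter` must run 1..J in order with no gaps.")
    }
  }
  season <- x[["season"]]
  if (is.null(season)) {
    if (is.null(x[["start_date"]])) {
      abort("`x` needs a `season` or `start_date` column.")
    }
    season <- assign_season(x$start_date, calendar)
  }
  accrual_series(
    count = x$count,
    season = season,
    duration = x[["duration"]] %||% 1,
    start_date = x[["start_date"]],
    trial_label = trial_label,
    excluded_count = excluded_count,
    calendar = calendar
  )
}

#' @export
print.accrual_series <- function(x, ...) {
  lbl <- attr(x, "trial_label")
  cat(sprintf(
    "# Accrual series%s: %d quarters, %d participants (exposure %.2f quarters)\n",
    if (is.null(lbl)) "" else paste0(" '", lbl, "'"),
    nrow(x), sum(x$count), sum(x$duration)
  ))
  exc <- attr(x, "excluded_count") %||% 0L
  if (exc > 0) {
    cat(sprintf("# plus %d participant(s) excluded from modeling\n", exc))
  }
  NextMethod()
}

#' Total participants observed, including any excluded from modeling
#' @noRd
observed_enrollment <- function(series) {
  sum(series$count) + (attr(series, "excluded_count") %||% 0L)
}

#' Per-season accrual summaries
#'
#' Splits a series into the four season sets: for each season, the quarter
#' indices that fall in it, the total count and the total exposure
#' (summed duration). Seasons with no quarters appear with zero totals, so
#' the four rows always partition the series.
#'
#' @param series An `accrual_series`.
#' @return A tibble with one row per season: `season`, `n_quarters`,
#'   `total_count`, `total_duration`, and list-column `quarters`.
#' @export
#' @examples
#' s <- accrual_series(count = rep(1, 8), season = "summer")
#' season_sets(s)
season_sets <- function(series) {
  series <- as_accrual_series(series)
  purrr::map_dfr(seasons(), function(s) {
    idx <- which(series$season == s)
    tibble::tibble(
      season = season_factor(s),
      n_quarters = length(idx),
      total_count = sum(series$count[idx]),
      total_duration = sum(series$duration[idx]),
      quarters = list(idx)
    )
  })
}

#' @exportS3Method ggplot2::autoplot
autoplot.accrual_series <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$quarter, y = .data$count, fill = .data$season)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Quarter", y = "Participants accrued",
      fill = "Season", title = attr(object, "trial_label")
    ) +
    ggplot2::theme_minimal()
}
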