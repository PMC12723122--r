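#' Aggregate monthly accrual records into seasonal quarters
#'
#' Monthly counts are summed into the meteorological quarter containing each
#' month's mid-point (the 16th), so under the default calendar summer
#' collects June/July/August, fall September/October/November, and so on.
#' The first quarter's duration is the fraction of the quarter covered from
#' `trial_start` to the quarter's end; when that fraction falls below
#' `partial_threshold` and `drop_partial_first` is set, the partial quarter
#' is removed and its count is carried on the result as `excluded_count`.
#' A trailing quarter with fewer than three months receives a duration of
#' (months present)/3.
#'
#' @param monthly A data frame with columns `month_start` (a date within each
#'   month; months must be contiguous) and `count` (non-negative integers).
#' @param trial_start Date enrollment opened; must fall inside the first
#'   month. Defaults to the first `month_start`.
#' @param drop_partial_first Drop the first quarter when its covered fraction
#'   is below `partial_threshold`? Default `TRUE`.
#' @param partial_threshold Covered fraction below which the first quarter is
#'   considered too incomplete to model. Default `0.5`.
#' @param full_first_quarter When the first quarter is retained, treat its
#'   duration as a full quarter (`t = 1`) rather than the exact day fraction.
#'   Default `TRUE`; set `FALSE` for exact-exposure accounting.
#' @param calendar A [season_calendar()].
#' @param trial_label Optional label attached to the result.
#' @return An `accrual_series`; participants dropped with a partial first
#'   quarter are recorded in its `excluded_count` attribute.
#' @export
#' @examples
#' monthly <- tibble::tibble(
#'   month_start = seq(as.Date("2019-08-01"), by = "month", length.out = 7),
#'   count = c(1, 4, 5, 3, 2, 4, 6)
#' )
#' quarterize(monthly, trial_start = as.Date("2019-08-15"))
quarterize <- function(monthly, trial_start = NULL,
                       drop_partial_first = TRUE, partial_threshold = 0.5,
                       full_first_quarter = TRUE,
                       calendar = season_calendar(), trial_label = NULL) {
  if (!is.data.frame(monthly) || nrow(monthly) == 0) {
    abort("`monthly` must be a non-empty data frame.")
  }
  if (!all(c("month_start", "count") %in% names(monthly))) {
    abort("`monthly` needs columns `month_start` and `count`.")
  }
  month_start <- as.Date(monthly$month_start)
  if (anyNA(month_start)) abort("`month_start` contains unparseable dates.")
  count <- monthly$count
  if (any(is.na(count)) || any(count < 0) || any(count != floor(count))) {
    abort("Monthly `count` values must be non-negative integers.")
  }

  ym <- as.integer(format(month_start, "%Y")) * 12L +
    as.integer(format(month_start, "%m")) - 1L
  if (is.unsorted(ym, strictly = TRUE)) {
    abort("Monthly records must be in chronological order with one row per month.")
  }
  gaps <- which(diff(ym) != 1L)
  if (length(gaps) > 0) {
    missing <- unlist(lapply(gaps, function(i) (ym[i] + 1L):(ym[i + 1L] - 1L)))
    abort(sprintf(
      "Monthly records are not contiguous; missing month(s): %s.",
      paste(sprintf("%04d-%02d", missing %/% 12L, missing %% 12L + 1L),
            collapse = ", ")
    ))
  }

  trial_start <- as.Date(trial_start %||% month_start[1])
  if (format(trial_start, "%Y-%m") != format(month_start[1], "%Y-%m")) {
    abort("`trial_start` must fall within the first month of the records.")
  }
  check_scalar_number(partial_threshold, "partial_threshold", 0, 1)

  # each month belongs to the quarter containing its 16th day
  mid <- as.Date(sprintf("%04d-%02d-16", ym %/% 12L, ym %% 12L + 1L))
  q_start <- quarter_start_date(mid, calendar)
  agg <- tibble::tibble(q_start = q_start, count = as.integer(count)) |>
    dplyr::group_by(.data$q_start) |>
    dplyr::summarise(
      count = sum(.data$count),
      n_months = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$q_start)

  q_end1 <- quarter_end_date(agg$q_start[1], calendar)
  frac1 <- as.numeric(q_end1 - trial_start) /
    as.numeric(q_end1 - agg$q_start[1])
  frac1 <- min(frac1, 1)

  excluded <- 0L
  if (drop_partial_first && nrow(agg) > 1 && frac1 < partial_threshold) {
    excluded <- agg$count[1]
    agg <- agg[-1, ]
    frac1 <- 1
  }

  durations <- rep(1, nrow(agg))
  durations[1] <- if (full_first_quarter) 1 else frac1
  # trailing quarter with missing months is pro-rated by months present
  last <- nrow(agg)
  if (last > 1 && agg$n_months[last] < 3L) {
    durations[last] <- agg$n_months[last] / 3
  }

  accrual_series(
    count = agg$count,
    season = assign_season(agg$q_start, calendar),
    duration = durations,
    start_date = agg$q_start,
    trial_label = trial_label,
    excluded_count = excluded,
    calendar = calendar
  )
}
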