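#' The four seasonal quarters
#'
#' Accrual time is discretised into meteorological quarters labelled
#' `"summer"`, `"fall"`, `"winter"` and `"spring"`, in that cyclic order
#' (summer is followed by fall, and spring wraps back to summer).
#'
#' @return Character vector of the four season labels in cyclic order.
#' @export
#' @examples
#' seasons()
seasons <- function() {
  c("summer", "fall", "winter", "spring")
}

#' Season factor with the canonical level order
#' @noRd
season_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), seasons())
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown season label(s): %s. Valid labels are %s.",
      paste(bad, collapse = ", "), paste(seasons(), collapse = ", ")
    ))
  }
  factor(x, levels = seasons())
}

#' The season that follows `season`, `n` steps around the cycle
#'
#' @param season A season label (or vector of labels).
#' @param n Integer number of steps forward (may be a vector).
#' @return Character season label(s).
#' @export
#' @examples
#' next_season("spring")       # wraps to summer
#' next_season("summer", 1:4)
next_season <- function(season, n = 1L) {
  idx <- match(as.character(season), seasons())
  if (anyNA(idx)) abort("Unknown season label.")
  seasons()[((idx - 1L + n) %% 4L) + 1L]
}

#' Define a season calendar by quarter start dates
#'
#' A season calendar maps each of the four labels to the month-day on which
#' that season's quarter begins. The default follows the mid-month
#' convention: quarters begin on the 16th of June (summer), September (fall),
#' December (winter) and March (spring), so e.g. summer runs from June 16
#' through September 15 inclusive. Southern-hemisphere or otherwise shifted
#' calendars are expressed by supplying different start dates.
#'
#' @param summer,fall,winter,spring Quarter start dates as `"MM-DD"` strings.
#' @return An object of class `season_calendar`.
#' @export
#' @examples
#' season_calendar()                          # northern mid-month default
#' season_calendar(
#'   summer = "12-16", fall = "03-16",
#'   winter = "06-16", spring = "09-16"
#' )                                          # southern hemisphere
season_calendar <- function(summer = "06-16", fall = "09-16",
                            winter = "12-16", spring = "03-16") {
  starts <- c(summer = summer, fall = fall, winter = winter, spring = spring)
  parsed <- lapply(starts, function(md) {
    m <- regmatches(md, regexec("^([0-1]?[0-9])-([0-3]?[0-9])$", md))[[1]]
    if (length(m) != 3) abort(sprintf("Invalid month-day '%s'; use 'MM-DD'.", md))
    month <- as.integer(m[2]); day <- as.integer(m[3])
    if (month < 1 || month > 12 || day < 1 || day > 31) {
      abort(sprintf("Invalid month-day '%s'.", md))
    }
    c(month = month, day = day)
  })
  keys <- vapply(parsed, function(p) p["month"] * 100L + p["day"], integer(1))
  if (anyDuplicated(keys)) abort("Season start dates must be distinct.")
  structure(
    list(starts = parsed, keys = sort(keys)),
    class = "season_calendar"
  )
}

#' @export
print.season_calendar <- function(x, ...) {
  cat("<season_calendar>\n")
  for (s in names(x$keys)) {
    k <- x$keys[[s]]
    cat(sprintf("  %-7s starts %02d-%02d\n", s, k %/% 100L, k %% 100L))
  }
  invisible(x)
}

#' Assign calendar dates to seasons
#'
#' Returns, for each date, the season whose quarter interval contains it.
#' Under the default calendar the boundaries fall on the 16th of March, June,
#' September and December: the 15th belongs to the ending season and the 16th
#' to the starting one. The assignment is periodic with period one year.
#'
#' @param date A `Date` vector (or anything `as.Date()` accepts).
#' @param calendar A [season_calendar()].
#' @return A factor with levels `seasons()`.
#' @export
#' @examples
#' assign_season(as.Date(c("2018-06-25", "2024-12-16", "2020-03-15")))
assign_season <- function(date, calendar = season_calendar()) {
  date <- as.Date(date)
  if (anyNA(date)) abort("`date` contains values that are not valid dates.")
  key <- as.integer(format(date, "%m")) * 100L + as.integer(format(date, "%d"))
  ks <- calendar$keys
  # season whose start is the most recent boundary at or before the date;
  # dates before the year's first boundary wrap to the previous year's last
  idx <- findInterval(key, ks)
  idx[idx == 0L] <- length(ks)
  season_factor(names(ks)[idx])
}

#' Start date of the quarter containing a date
#' @noRd
quarter_start_date <- function(date, calendar = season_calendar()) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  key <- as.integer(format(date, "%m")) * 100L + as.integer(format(date, "%d"))
  ks <- calendar$keys
  idx <- findInterval(key, ks)
  wrap <- idx == 0L
  idx[wrap] <- length(ks)
  yr[wrap] <- yr[wrap] - 1L
  k <- ks[idx]
  as.Date(sprintf("%04d-%02d-%02d", yr, k %/% 100L, k %% 100L))
}

#' First boundary date strictly after a date
#' @noRd
quarter_end_date <- function(date, calendar = season_calendar()) {
  start <- quarter_start_date(date, calendar)
  ks <- calendar$keys
  key <- as.integer(format(start, "%m")) * 100L + as.integer(format(start, "%d"))
  pos <- match(key, ks)
  yr <- as.integer(format(start, "%Y"))
  wrap <- pos == length(ks)
  nxt <- ifelse(wrap, 1L, pos + 1L)
  yr <- yr + as.integer(wrap)
  k <- ks[nxt]
  as.Date(sprintf("%04d-%02d-%02d", yr, k %/% 100L, k %% 100L))
}
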