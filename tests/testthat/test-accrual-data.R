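test_that("assign_season maps dates to mid-month quarters and is periodic", {
  expect_equal(as.character(assign_season(as.Date("2018-06-25"))), "summer")
  expect_equal(as.character(assign_season(as.Date("2024-12-16"))), "winter")
  expect_equal(as.character(assign_season(as.Date("2020-03-15"))), "winter")
  # boundary days: the 15th ends a season, the 16th starts the next
  expect_equal(
    as.character(assign_season(as.Date(c(
      "2021-03-16", "2021-06-15", "2021-06-16", "2021-09-15",
      "2021-09-16", "2021-12-15", "2021-12-16", "2022-03-15"
    )))),
    c("spring", "spring", "summer", "summer", "fall", "fall", "winter", "winter")
  )
  # periodic with period one year, constant within each quarter interval
  days <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
  shifted <- as.Date(sub("^2021", "2022", as.character(days)))
  expect_equal(assign_season(days), assign_season(shifted))
  # a custom (southern-hemisphere) calendar relabels the same boundaries
  south <- season_calendar(summer = "12-16", fall = "03-16",
                           winter = "06-16", spring = "09-16")
  expect_equal(as.character(assign_season(as.Date("2021-07-01"), south)), "winter")
})

test_that("quarterize aggregates months, prorates stubs, and drops partial first quarters", {
  # three months spanning exactly one quarter sum into a single full quarter
  m <- tibble::tibble(
    month_start = as.Date(c("2020-06-01", "2020-07-01", "2020-08-01")),
    count = c(2, 3, 4)
  )
  q <- quarterize(m, trial_start = as.Date("2020-06-16"))
  expect_equal(nrow(q), 1)
  expect_equal(q$count, 9L)
  expect_equal(q$duration, 1)
  expect_equal(as.character(q$season), "summer")

  # a trial starting mid-August with one enrollment before mid-September:
  # the ~1-month summer stub is dropped and its count reported as excluded
  m2 <- tibble::tibble(
    month_start = seq(as.Date("2019-08-01"), by = "month", length.out = 7),
    count = c(1, 10, 11, 12, 9, 8, 10)
  )
  q2 <- quarterize(m2, trial_start = as.Date("2019-08-15"))
  expect_equal(as.character(q2$season[1]), "fall")
  expect_equal(attr(q2, "excluded_count"), 1L)
  expect_equal(sum(q2$count), sum(m2$count) - 1L)

  # the same input with the partial quarter retained, exact-day durations
  q2b <- quarterize(m2, trial_start = as.Date("2019-08-15"),
                    drop_partial_first = FALSE, full_first_quarter = FALSE)
  expect_equal(as.character(q2b$season[1]), "summer")
  expect_equal(q2b$duration[1],
               as.numeric(as.Date("2019-09-16") - as.Date("2019-08-15")) / 92)
  expect_equal(attr(q2b, "excluded_count"), 0L)

  # a multi-year monthly history starting late June 2018 and running through
  # November 2024 spans exactly 26 full quarters, summer first
  m3 <- tibble::tibble(
    month_start = seq(as.Date("2018-06-01"), as.Date("2024-11-01"), by = "month"),
    count = 5
  )
  q3 <- quarterize(m3, trial_start = as.Date("2018-06-25"))
  expect_equal(nrow(q3), 26)
  expect_equal(as.character(q3$season[1]), "summer")
  expect_true(all(q3$duration == 1))

  # rejection with a gap report
  gap <- m[-2, ]
  expect_error(quarterize(gap), "2020-07")
  expect_error(quarterize(m[0, ]), "non-empty")
})

test_that("quarterize round-trips counts from a known quarterly series", {
  set.seed(42)
  true_counts <- rpois(12, 8)
  # each quarter starting at the 16th collects the three months whose 16th
  # falls inside it; split each quarter's count across those months
  q_starts <- seq(as.Date("2020-06-16"), by = "3 months", length.out = 12)
  monthly <- purrr::map_dfr(seq_along(q_starts), function(i) {
    months <- seq(q_starts[i], by = "month", length.out = 3)
    split <- c(rmultinom(1, true_counts[i], rep(1 / 3, 3)))
    tibble::tibble(month_start = as.Date(format(months, "%Y-%m-01")), count = split)
  })
  q <- quarterize(monthly, trial_start = as.Date("2020-06-16"))
  expect_equal(q$count, as.integer(true_counts))
  expect_equal(as.character(q$season[1]), "summer")
})

test_that("season_sets partitions counts and exposure exactly", {
  s26 <- fixture_series(c(summer = 48, fall = 42, winter = 22, spring = 27),
                        26, "summer")
  ss <- season_sets(s26)
  expect_equal(ss$n_quarters, c(7L, 7L, 6L, 6L))
  expect_equal(sum(ss$total_count), sum(s26$count))
  expect_equal(sum(ss$total_duration), sum(s26$duration))
  expect_equal(sort(unlist(ss$quarters)), 1:26)

  s21 <- fixture_series(c(summer = 10, fall = 12, winter = 9, spring = 11),
                        21, "fall")
  ss21 <- season_sets(s21)
  expect_equal(
    setNames(ss21$n_quarters, as.character(ss21$season)),
    c(summer = 5L, fall = 6L, winter = 5L, spring = 5L)
  )

  one <- accrual_series(count = 4, season = "winter")
  ss1 <- season_sets(one)
  expect_equal(ss1$total_count[ss1$season == "winter"], 4)
  expect_equal(sum(ss1$n_quarters), 1L)

  # partition holds for arbitrary generated series with partial durations
  for (seed in 1:5) {
    g <- generate_series(c(summer = 9, fall = 7, winter = 3, spring = 5),
                         n_quarters = 17, durations = runif(17, 0.2, 1),
                         start_season = "winter", seed = seed)
    gs <- season_sets(g)
    expect_equal(sum(gs$total_count), sum(g$count))
    expect_equal(sum(gs$total_duration), sum(g$duration))
  }
})

test_that("accrual series validation enforces the data contract", {
  expect_error(accrual_series(count = -1, season = "summer"), "non-negative")
  expect_error(accrual_series(count = 1.5, season = "summer"), "non-negative")
  expect_error(accrual_series(count = 1, season = "summer", duration = 0), "0, 1")
  expect_error(accrual_series(count = 1, season = "monsoon"), "Unknown season")
  expect_error(
    accrual_series(count = 1, season = "winter",
                   start_date = as.Date("2021-07-01")),
    "disagrees"
  )
  # a single starting label is continued around the cycle
  s <- accrual_series(count = rep(1, 6), season = "winter")
  expect_equal(as.character(s$season),
               c("winter", "spring", "summer", "fall", "winter", "spring"))
})
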