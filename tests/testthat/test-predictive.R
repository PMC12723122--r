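test_that("predictive totals are bounded below and reproducible", {
  fit <- fit_accrual(hobit_series(), hobit_prior(), model = "homogeneous")
  p1 <- predict_total(fit, horizon_q = 36, replicates = 5000, seed = 21)
  expect_equal(length(p1$totals), 5000)
  expect_true(all(p1$totals >= 139))
  p2 <- predict_total(fit, horizon_q = 36, replicates = 5000, seed = 21)
  expect_identical(p1$totals, p2$totals)

  # zero future quarters: every draw equals the observed total
  p0 <- predict_total(fit, horizon_q = 26, replicates = 100, seed = 1)
  expect_true(all(p0$totals == 139))
  s0 <- summarize_predictive(p0)
  expect_equal(c(s0$lower, s0$upper), c(139, 139))

  expect_error(predict_total(fit, horizon_q = 36, replicates = 0), "replicates")
  expect_error(predict_total(fit, horizon_q = 10), "horizon_q")
})

test_that("predictive mean converges to observed + exposure x posterior mean", {
  fit <- fit_accrual(hobit_series(), hobit_prior(), model = "homogeneous")
  R <- 3e5
  p <- predict_total(fit, horizon_q = 36, replicates = R, seed = 8)
  mu <- 145.25 / 26.5
  sig2 <- 145.25 / 26.5^2
  expect_lt(
    abs(mean(p$totals) - (139 + 10 * mu)),
    4 * sqrt((10 * mu + 100 * sig2) / R)
  )
  # variance law under the shared-draw scheme: T*mu + T^2 * sigma^2
  v_true <- 10 * mu + 100 * sig2
  expect_lt(abs(stats::var(p$totals) / v_true - 1), 0.05)

  # the per-quarter-draw scheme has strictly smaller between-quarter
  # correlation, hence smaller variance: T*mu + T*sigma^2
  pq <- predict_total(fit, horizon_q = 36, replicates = R, seed = 8,
                      scheme = "per_quarter")
  v_pq <- 10 * mu + 10 * sig2
  expect_lt(abs(stats::var(pq$totals) / v_pq - 1), 0.05)
  expect_lt(stats::var(pq$totals), stats::var(p$totals))
})

test_that("seasonal prediction with identical posteriors matches the homogeneous model", {
  prior <- gamma_prior(50, 10)
  hom <- fit_accrual(NULL, prior, model = "homogeneous")
  sea <- fit_accrual(NULL, prior, model = "seasonal")
  fq <- tibble::tibble(season = next_season("summer", 1:8), duration = 1)
  R <- 40000

  # under the per-quarter-draw scheme the two models induce the same
  # distribution over totals when all four seasonal posteriors are identical
  ph <- predict_total(hom, future_quarters = fq, observed_total = 0,
                      replicates = R, seed = 31, scheme = "per_quarter")
  ps <- predict_total(sea, future_quarters = fq, observed_total = 0,
                      replicates = R, seed = 32, scheme = "per_quarter")
  se_mean <- sqrt(stats::var(ph$totals) / R + stats::var(ps$totals) / R)
  expect_lt(abs(mean(ph$totals) - mean(ps$totals)), 4 * se_mean)
  expect_lt(abs(stats::sd(ph$totals) / stats::sd(ps$totals) - 1), 0.05)

  # under the shared-draw scheme the means still agree, but the homogeneous
  # model shares one rate draw across all 8 quarters while the seasonal model
  # shares one draw per season (2 quarters each), so its totals have smaller
  # variance: T*mu + T^2*s2 = 8*5 + 64*0.5 vs T*mu + sum_s T_s^2*s2 = 40 + 8
  mu <- 5; s2 <- 0.5
  ph2 <- predict_total(hom, future_quarters = fq, observed_total = 0,
                       replicates = R, seed = 33)
  ps2 <- predict_total(sea, future_quarters = fq, observed_total = 0,
                       replicates = R, seed = 34)
  se_mean2 <- sqrt(stats::var(ph2$totals) / R + stats::var(ps2$totals) / R)
  expect_lt(abs(mean(ph2$totals) - mean(ps2$totals)), 4 * se_mean2)
  expect_lt(abs(stats::var(ph2$totals) / (8 * mu + 64 * s2) - 1), 0.05)
  expect_lt(abs(stats::var(ps2$totals) / (8 * mu + 16 * s2) - 1), 0.05)
})

test_that("seasonal prediction continues the calendar and reproduces trial-scale means", {
  fit <- fit_accrual(hobit_series(), hobit_prior(), model = "seasonal")
  p <- predict_total(fit, horizon_q = 36, replicates = 10000, seed = 13)
  # quarter 26 of a summer-start series is a fall, so the 10 future quarters
  # run winter, spring, summer, fall, ... , spring
  expect_equal(as.character(p$future_quarters$season[1]), "winter")
  expect_equal(as.character(p$future_quarters$season[10]), "spring")
  # analytic expectation: observed + sum over future quarters of the
  # corresponding seasonal posterior means
  post <- fit$posterior
  mu_s <- setNames(post$shape / post$rate, as.character(post$season))
  expected <- 139 + sum(mu_s[as.character(p$future_quarters$season)])
  expect_lt(abs(mean(p$totals) - expected), 1.5)  # well within MC error
  # published simulation-based mean 194.6: both sides are 10,000-draw MC
  # summaries of the seasonal predictive, so allow combined MC error plus
  # the printed rounding resolution (sd of totals ~ 8.7 -> SE ~ 0.09)
  expect_lt(abs(expected - 194.6),
            3 * sqrt(2) * stats::sd(p$totals) / sqrt(10000) + 0.05)
})

test_that("summarize_predictive returns coherent summaries and histogram", {
  fit <- fit_accrual(boost3_series(), boost3_prior(), model = "homogeneous")
  p <- predict_total(fit, horizon_q = 30, replicates = 10000, seed = 4)
  s <- summarize_predictive(p, level = 0.95)
  expect_equal(sum(s$histogram$frequency), 10000)
  expect_equal(
    sum(s$histogram$total * s$histogram$frequency) / 10000,
    s$mean
  )
  expect_lte(s$lower, s$mean)
  expect_gte(s$upper, s$mean)
  # glance/tidy accessors agree with the summary
  g <- glance(p)
  expect_equal(g$mean, s$mean)
  expect_equal(nrow(tidy(p)), 10000)
})
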