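test_that("prior elicitation scales the planned rate by the confidence level", {
  p1 <- elicit_prior(200, 16, 0.5)
  expect_equal(p1$shape, 6.25)
  expect_equal(p1$rate, 0.5)
  p2 <- elicit_prior(1094, 16, 0.5)
  expect_equal(p2$shape, 1094 / 16 * 0.5) # = 34.1875 exactly
  expect_lt(abs(p2$shape - 34.18), 0.01)  # published rounded value
  expect_equal(p2$rate, 0.5)
  p3 <- elicit_prior(100, 10, 1.0)
  expect_equal(p3$shape, 10)
  expect_equal(p3$rate, 1)
  expect_equal(p3$shape / p3$rate, 10) # prior mean equals the planned rate
  expect_error(elicit_prior(100, 10, 0), "confidence_p")
  expect_error(elicit_prior(100, 10, 1.2), "confidence_p")
})

test_that("homogeneous conjugate update adds counts to shape and exposure to rate", {
  fit <- fit_accrual(hobit_series(), hobit_prior(), model = "homogeneous")
  expect_equal(fit$posterior$shape, 6.25 + 139)
  expect_equal(fit$posterior$rate, 0.5 + 26)
  expect_equal(fit$posterior$shape / fit$posterior$rate, 145.25 / 26.5)

  fitb <- fit_accrual(boost3_series(), boost3_prior(), model = "homogeneous")
  expect_equal(fitb$posterior$shape, 34.18 + 724)
  expect_equal(fitb$posterior$rate, 0.5 + 21)
  expect_equal(round(fitb$posterior$shape / fitb$posterior$rate, 2), 35.26)

  # no-data identity: the posterior of a prior-only fit is the prior
  fit0 <- fit_accrual(NULL, gamma_prior(3.2, 0.7), model = "homogeneous")
  expect_equal(fit0$posterior$shape, 3.2)
  expect_equal(fit0$posterior$rate, 0.7)
})

test_that("seasonal update reproduces published seasonal posterior means", {
  fit <- fit_accrual(hobit_series(), hobit_prior(), model = "seasonal")
  means <- setNames(fit$posterior$shape / fit$posterior$rate,
                    as.character(fit$posterior$season))
  expect_equal(round(unname(means[c("summer", "fall", "winter", "spring")]), 2),
               c(7.23, 6.43, 4.35, 5.12))
  # published simulation-based means 7.22/6.43/4.33/5.11 within MC error
  expect_true(all(abs(means[c("summer", "fall", "winter", "spring")] -
                        c(7.22, 6.43, 4.33, 5.11)) < 0.05))

  fitb <- fit_accrual(boost3_series(), boost3_prior(), model = "seasonal")
  meansb <- setNames(fitb$posterior$shape / fitb$posterior$rate,
                     as.character(fitb$posterior$season))
  expect_true(all(abs(meansb[c("summer", "fall", "winter", "spring")] -
                        c(45.67, 37.41, 35.46, 31.10)) < 0.05))

  # a series entirely in one season updates only that season
  one <- accrual_series(count = c(5, 7), season = c("winter", "winter"),
                        duration = c(1, 1))
  f1 <- fit_accrual(one, gamma_prior(2, 0.5), model = "seasonal")
  post <- f1$posterior
  expect_equal(post$shape[post$season == "winter"], 2 + 12)
  expect_equal(post$shape[post$season != "winter"], rep(2, 3))
  expect_equal(post$rate[post$season != "winter"], rep(0.5, 3))
  expect_true(all(posterior_summary(f1)$prior_only[post$season != "winter"]))
})

test_that("updating with concatenated data equals sequential posterior chaining", {
  s <- generate_series(c(summer = 9, fall = 6, winter = 3, spring = 5),
                       n_quarters = 15, durations = c(rep(1, 14), 0.4),
                       seed = 11)
  prior <- gamma_prior(4, 0.8)
  full <- fit_accrual(s, prior, model = "homogeneous")
  first <- accrual_series(count = s$count[1:7], season = s$season[1:7],
                          duration = s$duration[1:7])
  second <- accrual_series(count = s$count[8:15], season = s$season[8:15],
                           duration = s$duration[8:15])
  step1 <- fit_accrual(first, prior, model = "homogeneous")
  step2 <- fit_accrual(second,
                       gamma_prior(step1$posterior$shape, step1$posterior$rate),
                       model = "homogeneous")
  expect_equal(step2$posterior$shape, full$posterior$shape)
  expect_equal(step2$posterior$rate, full$posterior$rate)
})

test_that("single-season data makes the seasonal posterior match the homogeneous one", {
  s <- accrual_series(count = c(4, 9, 2), season = rep("spring", 3),
                      duration = c(1, 0.5, 1))
  prior <- gamma_prior(3, 0.6)
  hom <- fit_accrual(s, prior, model = "homogeneous")$posterior
  sea <- fit_accrual(s, prior, model = "seasonal")$posterior
  sp <- sea[sea$season == "spring", ]
  expect_equal(sp$shape, hom$shape)
  expect_equal(sp$rate, hom$rate)
})

test_that("adding a quarter accruing above the posterior mean raises the mean", {
  s <- accrual_series(count = c(3, 4, 2), season = "summer")
  prior <- gamma_prior(2, 0.5)
  fit <- fit_accrual(s, prior, model = "homogeneous")
  mean0 <- fit$posterior$shape / fit$posterior$rate
  m_new <- ceiling(mean0) + 1L
  s2 <- accrual_series(count = c(s$count, m_new), season = "summer")
  fit2 <- fit_accrual(s2, prior, model = "homogeneous")
  expect_gt(fit2$posterior$shape / fit2$posterior$rate, mean0)
})

test_that("posterior summaries: analytic closed forms and Monte-Carlo convergence", {
  # exponential special case Gamma(1, 1)
  f <- fit_accrual(NULL, gamma_prior(1, 1))
  s <- posterior_summary(f, level = 0.95)
  expect_equal(s$mean, 1)
  expect_equal(s$lower, -log(0.975))
  expect_equal(s$upper, -log(0.025))

  fh <- fit_accrual(hobit_series(), hobit_prior(), model = "homogeneous")
  sh <- posterior_summary(fh)
  expect_equal(sh$lower, qgamma(0.025, 145.25, rate = 26.5))
  expect_equal(sh$upper, qgamma(0.975, 145.25, rate = 26.5))
  expect_error(posterior_summary(fh, level = 1.2), "level")

  # empirical quantiles at many draws agree with analytic quantiles within
  # 3 Monte-Carlo standard errors (density-at-quantile approximation)
  draws <- sample_rate(fh, draws = 1e6, seed = 5)$rate
  for (p in c(0.025, 0.975)) {
    q_true <- qgamma(p, 145.25, rate = 26.5)
    se <- sqrt(p * (1 - p) / 1e6) / dgamma(q_true, 145.25, rate = 26.5)
    expect_lt(abs(quantile(draws, p, names = FALSE) - q_true), 3 * se)
  }
  expect_lt(abs(mean(draws) - 145.25 / 26.5),
            3 * sqrt(145.25 / 26.5^2 / 1e6))
})

test_that("posterior rate draws are reproducible and scale correctly", {
  f <- fit_accrual(NULL, gamma_prior(5, 2))
  one <- sample_rate(f, draws = 1, seed = 99)
  expect_identical(one, sample_rate(f, draws = 1, seed = 99))
  # Gamma(a, b) draws scaled by b are distributed Gamma(a, 1)
  x <- sample_rate(f, draws = 20000, seed = 3)$rate
  ks <- suppressWarnings(stats::ks.test(x * 2, stats::pgamma, 5, 1))
  expect_gt(ks$p.value, 1e-3)
})
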