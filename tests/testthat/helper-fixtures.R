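# Fixtures and independent oracles used across the suite.

# Build a series whose per-season totals are fixed, spreading each season's
# total as evenly as possible over that season's quarters. The conjugate
# posteriors depend on the data only through per-season totals and exposures,
# so any spread reproduces the same posterior.
fixture_series <- function(season_totals, n_quarters, start_season) {
  seas <- next_season(start_season, 0:(n_quarters - 1L))
  counts <- integer(n_quarters)
  for (s in names(season_totals)) {
    idx <- which(seas == s)
    base <- season_totals[[s]] %/% length(idx)
    counts[idx] <- base
    rem <- season_totals[[s]] - base * length(idx)
    if (rem > 0) counts[idx[seq_len(rem)]] <- base + 1L
  }
  accrual_series(count = counts, season = seas)
}

# Slow-accruing trial: 139 modeled participants over 26 unit quarters from
# summer; per-season totals recovered by inverting the conjugate posterior
# mean formula against the published seasonal means.
hobit_series <- function() {
  fixture_series(
    c(summer = 48, fall = 42, winter = 22, spring = 27),
    n_quarters = 26, start_season = "summer"
  )
}
hobit_prior <- function() gamma_prior(6.25, 0.5)

# Fast-accruing trial: 724 modeled participants over 21 unit quarters from
# fall (one further participant was excluded with a partial first quarter).
boost3_series <- function() {
  s <- fixture_series(
    c(summer = 217, fall = 209, winter = 161, spring = 137),
    n_quarters = 21, start_season = "fall"
  )
  attr(s, "excluded_count") <- 1L
  s
}
boost3_prior <- function() gamma_prior(34.18, 0.5)

# Independent quadrature oracle for P(X > Y), X ~ Gamma(a1, b1) and
# Y ~ Gamma(a2, b2) independent (rate parameterization).
prob_gt_quad <- function(a1, b1, a2, b2) {
  stats::integrate(
    function(y) stats::dgamma(y, a2, rate = b2) *
      stats::pgamma(y, a1, rate = b1, lower.tail = FALSE),
    0, Inf, rel.tol = 1e-10
  )$value
}

# Monte-Carlo standard error of an empirical quantile, via the normal
# density approximation at the quantile.
quantile_se <- function(draws, p) {
  q <- stats::quantile(draws, p, names = FALSE)
  f <- stats::dnorm((q - mean(draws)) / stats::sd(draws)) / stats::sd(draws)
  sqrt(p * (1 - p) / length(draws)) / f
}

# Exact two-sided binomial band for a proportion estimated from n draws.
# Evaluates qbinom on the rarer tail: qbinom is numerically unreliable for
# tiny quantiles when prob is close to 1.
binom_band <- function(p, n, alpha) {
  if (p <= 0.5) {
    c(stats::qbinom(alpha, n, p), stats::qbinom(1 - alpha, n, p)) / n
  } else {
    q <- 1 - p
    1 - rev(c(stats::qbinom(alpha, n, q), stats::qbinom(1 - alpha, n, q))) / n
  }
}
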