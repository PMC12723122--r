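#' Probability that one season's accrual rate exceeds another's
#'
#' For independent gamma posteriors \eqn{\lambda_s \sim Gamma(a_s, b_s)} and
#' \eqn{\lambda_k \sim Gamma(a_k, b_k)}, computes \eqn{P(\lambda_s >
#' \lambda_k)} either by Monte Carlo (fraction of joint draws with a strict
#' exceedance) or in closed form via the beta transform
#' \eqn{P(\lambda_s > \lambda_k) = P\{B > b_s/(b_s+b_k)\}} with
#' \eqn{B \sim Beta(a_s, a_k)} — the identity follows from
#' \eqn{b_s\lambda_s / (b_s\lambda_s + b_k\lambda_k) \sim Beta(a_s, a_k)}.
#'
#' @param fit A seasonal [fit_accrual()] result.
#' @param s,k Distinct season labels; the probability is that `s`'s rate
#'   exceeds `k`'s.
#' @param draws Number of joint posterior draws for the Monte-Carlo method.
#' @param seed Optional integer seed.
#' @param method `"monte_carlo"` (default, matches [compare_seasons()]) or
#'   `"closed_form"` (exact).
#' @return A single probability.
#' @export
#' @examples
#' fit <- fit_accrual(
#'   accrual_series(count = c(9, 2, 1, 4), season = "summer"),
#'   gamma_prior(2, 0.5), model = "seasonal"
#' )
#' pairwise_prob(fit, "summer", "winter", method = "closed_form")
pairwise_prob <- function(fit, s, k, draws = 10000, seed = NULL,
                          method = c("monte_carlo", "closed_form")) {
  stopifnot(inherits(fit, "accrual_fit"))
  if (fit$model != "seasonal") abort("`fit` must be a seasonal model fit.")
  method <- match.arg(method)
  s <- as.character(season_factor(s))
  k <- as.character(season_factor(k))
  if (identical(s, k)) abort("`s` and `k` must be different seasons.")
  post <- fit$posterior
  i <- match(s, as.character(post$season))
  j <- match(k, as.character(post$season))
  if (method == "closed_form") {
    pbeta(post$rate[i] / (post$rate[i] + post$rate[j]),
          post$shape[i], post$shape[j], lower.tail = FALSE)
  } else {
    check_scalar_number(draws, "draws", 1)
    lam <- sample_rate_matrix(fit, draws, seed)
    mean(lam[, s] > lam[, k])
  }
}

#' Probability that each season has the highest / lowest accrual rate
#'
#' From one shared matrix of joint posterior draws, the fraction of draws in
#' which each season's rate is strictly the largest (`prob_max`) and strictly
#' the smallest (`prob_min`).
#'
#' @inheritParams pairwise_prob
#' @return A tibble with one row per season: `season`, `prob_max`, `prob_min`.
#' @export
prob_extreme_season <- function(fit, draws = 10000, seed = NULL) {
  stopifnot(inherits(fit, "accrual_fit"))
  if (fit$model != "seasonal") abort("`fit` must be a seasonal model fit.")
  check_scalar_number(draws, "draws", 1)
  lam <- sample_rate_matrix(fit, draws, seed)
  extreme_from_draws(lam)
}

extreme_from_draws <- function(lam) {
  # ties have probability zero in theory; in floating point they are counted
  # as "not strictly extreme"
  row_max <- do.call(pmax, as.data.frame(lam))
  row_min <- do.call(pmin, as.data.frame(lam))
  at_max <- lam == row_max
  at_min <- lam == row_min
  strict_max <- at_max & rowSums(at_max) == 1L
  strict_min <- at_min & rowSums(at_min) == 1L
  tibble::tibble(
    season = season_factor(colnames(lam)),
    prob_max = colMeans(strict_max),
    prob_min = colMeans(strict_min)
  )
}

#' Compare all seasonal accrual rates from one set of joint draws
#'
#' Computes the full 4x4 table of pairwise exceedance probabilities and the
#' highest-/lowest-rate probabilities from a SINGLE shared matrix of joint
#' posterior draws, so the complement identity
#' `P(s > k) = 1 - P(k > s)` and the coherence bound
#' `prob_max(s) <= min_k P(s > k)` hold exactly on the output rather than
#' only in the Monte-Carlo limit.
#'
#' @inheritParams pairwise_prob
#' @return An object of class `season_comparison` with elements `pairwise`
#'   (4x4 matrix, entry (s, k) = P(rate of s > rate of k)), `extreme` (tibble
#'   from [prob_extreme_season()]), `draws` and `seed`. `tidy()` returns the
#'   pairwise table in long format.
#' @export
#' @examples
#' fit <- fit_accrual(
#'   generate_series(c(summer = 9, fall = 6, winter = 3, spring = 5),
#'                   n_quarters = 24, seed = 7),
#'   gamma_prior(6.25, 0.5), model = "seasonal"
#' )
#' compare_seasons(fit, draws = 2000, seed = 1)
compare_seasons <- function(fit, draws = 10000, seed = NULL) {
  stopifnot(inherits(fit, "accrual_fit"))
  if (fit$model != "seasonal") abort("`fit` must be a seasonal model fit.")
  check_scalar_number(draws, "draws", 1)
  lam <- sample_rate_matrix(fit, draws, seed)
  nm <- colnames(lam)
  pw <- matrix(NA_real_, 4, 4, dimnames = list(nm, nm))
  for (i in seq_len(4)) {
    for (j in seq_len(4)) {
      if (i != j) pw[i, j] <- mean(lam[, i] > lam[, j])
    }
  }
  structure(
    list(pairwise = pw, extreme = extreme_from_draws(lam),
         draws = nrow(lam), seed = seed),
    class = "season_comparison"
  )
}

#' @export
print.season_comparison <- function(x, ...) {
  cat(sprintf(
    "<season_comparison> P(row rate > column rate), %d joint draws\n", x$draws
  ))
  print(round(x$pairwise, 3))
  cat("\n")
  print(x$extreme)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.season_comparison <- function(x, ...) {
  grid <- expand.grid(
    season = rownames(x$pairwise), other = colnames(x$pairwise),
    stringsAsFactors = FALSE
  )
  grid <- grid[grid$season != grid$other, ]
  tibble::tibble(
    season = season_factor(grid$season),
    other = season_factor(grid$other),
    prob_greater = x$pairwise[cbind(grid$season, grid$other)]
  )
}

#' @exportS3Method generics::glance
glance.season_comparison <- function(x, ...) {
  e <- x$extreme
  tibble::tibble(
    draws = x$draws,
    top_season = e$season[which.max(e$prob_max)],
    top_prob = max(e$prob_max),
    bottom_season = e$season[which.max(e$prob_min)],
    bottom_prob = max(e$prob_min)
  )
}
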