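#' Simulate the posterior predictive distribution of total accrual
#'
#' For each of `replicates` simulation replicates, rates are drawn from the
#' fitted posterior and independent Poisson counts are generated for every
#' future quarter; the replicate's total is the observed enrollment plus the
#' simulated future counts. Under the default `scheme = "shared"` ONE rate
#' value per rate parameter (one overall, or one per season) is drawn per
#' replicate and shared across all of that replicate's future quarters,
#' which propagates rate uncertainty into between-quarter correlation.
#' `scheme = "per_quarter"` redraws the rate for every future quarter, giving
#' narrower (and, for planning, overconfident) predictive intervals; it is
#' provided for comparison.
#'
#' @param fit An [fit_accrual()] result.
#' @param horizon_q Total number of quarters (observed plus future) the
#'   prediction should cover; must be at least the number observed.
#'   Alternatively give `future_quarters` directly.
#' @param future_quarters Optional tibble with columns `season` and
#'   `duration` describing the future quarters explicitly. When omitted,
#'   `horizon_q - J` unit-duration quarters are generated continuing the
#'   seasonal cycle after the last observed quarter.
#' @param observed_total Observed enrollment added to every replicate.
#'   Defaults to the series total including any participants excluded from
#'   modeling (they still count toward enrollment).
#' @param replicates Number of simulation replicates (default 10000).
#' @param seed Optional integer seed.
#' @param scheme `"shared"` (default) or `"per_quarter"`; see Details.
#' @param level Credible level for the summary interval.
#' @return An object of class `accrual_prediction` holding the vector of
#'   simulated totals and its summaries; see [summarize_predictive()],
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' fit <- fit_accrual(NULL, gamma_prior(145.25, 26.5))
#' predict_total(fit, future_quarters = tibble::tibble(
#'   season = next_season("fall", 1:10), duration = 1
#' ), observed_total = 139, replicates = 2000, seed = 42)
predict_total <- function(fit, horizon_q = NULL, future_quarters = NULL,
                          observed_total = NULL, replicates = 10000,
                          seed = NULL, scheme = c("shared", "per_quarter"),
                          level = 0.95) {
  stopifnot(inherits(fit, "accrual_fit"))
  scheme <- match.arg(scheme)
  check_scalar_number(replicates, "replicates", 1)
  replicates <- as.integer(replicates)
  J <- if (is.null(fit$series)) 0L else nrow(fit$series)

  if (is.null(future_quarters)) {
    if (is.null(horizon_q)) abort("Supply `horizon_q` or `future_quarters`.")
    check_scalar_number(horizon_q, "horizon_q", J)
    n_future <- as.integer(horizon_q) - J
    last_season <- if (J > 0) {
      as.character(fit$series$season[J])
    } else {
      "spring" # so continuation starts at summer
    }
    future_quarters <- tibble::tibble(
      season = if (n_future > 0) {
        season_factor(next_season(last_season, seq_len(n_future)))
      } else {
        season_factor(character(0))
      },
      duration = rep(1, n_future)
    )
  } else {
    future_quarters <- tibble::as_tibble(future_quarters)
    if (!all(c("season", "duration") %in% names(future_quarters))) {
      abort("`future_quarters` needs `season` and `duration` columns.")
    }
    future_quarters$season <- season_factor(future_quarters$season)
    if (any(future_quarters$duration <= 0 | future_quarters$duration > 1)) {
      abort("Future quarter durations must lie in (0, 1].")
    }
  }

  if (is.null(observed_total)) {
    observed_total <- if (is.null(fit$series)) 0L else observed_enrollment(fit$series)
  }
  check_scalar_number(observed_total, "observed_total", 0)

  totals <- with_seed_opt(seed, {
    simulate_future_totals(fit, future_quarters, replicates, scheme)
  }) + observed_total

  new_accrual_prediction(
    totals = totals, observed_total = observed_total,
    future_quarters = future_quarters, model = fit$model,
    replicates = replicates, seed = seed, scheme = scheme, level = level
  )
}

#' Simulate future-count totals (without the observed offset); assumes the
#' RNG state is already set by the caller.
#' @noRd
simulate_future_totals <- function(fit, future_quarters, replicates, scheme) {
  n_future <- nrow(future_quarters)
  if (n_future == 0) return(rep(0L, replicates))
  post <- fit$posterior
  if (fit$model == "homogeneous") {
    col_idx <- rep(1L, n_future)
  } else {
    col_idx <- match(as.character(future_quarters$season),
                     as.character(post$season))
  }
  t_j <- future_quarters$duration

  if (scheme == "shared") {
    # one rate draw per replicate per rate parameter, shared across quarters
    lam <- vapply(seq_len(nrow(post)),
                  function(i) rgamma(replicates, post$shape[i], rate = post$rate[i]),
                  numeric(replicates))
    lam <- matrix(lam, nrow = replicates)
    means <- lam[, col_idx, drop = FALSE] *
      matrix(t_j, nrow = replicates, ncol = n_future, byrow = TRUE)
  } else {
    # an independent rate draw for every (replicate, future quarter) pair
    means <- vapply(seq_len(n_future), function(j) {
      i <- col_idx[j]
      rgamma(replicates, post$shape[i], rate = post$rate[i]) * t_j[j]
    }, numeric(replicates))
    means <- matrix(means, nrow = replicates)
  }
  counts <- matrix(rpois(replicates * n_future, means), nrow = replicates)
  as.integer(rowSums(counts))
}

new_accrual_prediction <- function(totals, observed_total, future_quarters,
                                   model, replicates, seed, scheme, level) {
  structure(
    list(
      totals = totals, observed_total = observed_total,
      future_quarters = future_quarters, model = model,
      replicates = replicates, seed = seed, scheme = scheme, level = level
    ),
    class = "accrual_prediction"
  )
}

#' Summarize a predictive simulation
#'
#' @param prediction An [predict_total()] result.
#' @param level Credible level for the equal-tailed interval.
#' @return A list with `mean`, `lower`, `upper`, `level`, `replicates`, and
#'   `histogram`, a tibble mapping each achieved total to its frequency.
#' @export
summarize_predictive <- function(prediction, level = prediction$level) {
  stopifnot(inherits(prediction, "accrual_prediction"))
  check_scalar_number(level, "level", 0, 1, open_lower = TRUE, open_upper = TRUE)
  totals <- prediction$totals
  if (length(totals) == 0) abort("Prediction holds no draws.")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- quantile(totals, probs, names = FALSE, type = 7)
  tab <- table(totals)
  list(
    mean = mean(totals),
    lower = qs[1],
    upper = qs[2],
    level = level,
    replicates = length(totals),
    histogram = tibble::tibble(
      total = as.integer(names(tab)),
      frequency = as.integer(tab)
    )
  )
}

#' @export
print.accrual_prediction <- function(x, ...) {
  s <- summarize_predictive(x)
  cat(sprintf(
    paste0(
      "<accrual_prediction> %s model, %d replicates (%s-draw scheme)\n",
      "  observed %s + %d future quarters\n",
      "  predicted total: mean %.1f, %g%% interval [%.0f, %.0f]\n"
    ),
    x$model, x$replicates, sub("_", "-", x$scheme),
    format(x$observed_total), nrow(x$future_quarters),
    s$mean, 100 * s$level, s$lower, s$upper
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.accrual_prediction <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$totals), total = x$totals)
}

#' @exportS3Method generics::glance
glance.accrual_prediction <- function(x, level = x$level, ...) {
  s <- summarize_predictive(x, level)
  tibble::tibble(
    model = x$model, scheme = x$scheme,
    mean = s$mean, lower = s$lower, upper = s$upper, level = s$level,
    replicates = s$replicates, observed_total = x$observed_total,
    n_future = nrow(x$future_quarters)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.accrual_prediction <- function(object, ...) {
  s <- summarize_predictive(object)
  ggplot2::ggplot(
    s$histogram,
    ggplot2::aes(x = .data$total, y = .data$frequency)
  ) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_vline(xintercept = s$mean, linetype = 2) +
    ggplot2::labs(
      x = "Total accrual", y = "Replicates",
      title = sprintf("Posterior predictive total (%s model)", object$model)
    ) +
    ggplot2::theme_minimal()
}
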