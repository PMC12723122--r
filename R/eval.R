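#' Poisson deviance of an accrual series at given rates
#'
#' Minus twice the Poisson log-likelihood of the observed counts,
#' \eqn{-2 \sum_j \log PoissonPMF(m_j; \lambda_{S(j)} t_j)}, including the
#' \eqn{\log(m_j!)} normalisation so absolute values are comparable with
#' BUGS-style deviance output. A single rate applies to all quarters
#' (homogeneous); a named vector over seasons applies season-specifically.
#'
#' @param series An `accrual_series`.
#' @param rates A single positive rate, or a vector named by season labels.
#' @return The deviance (a single number).
#' @export
#' @examples
#' s <- accrual_series(count = 2, season = "summer")
#' accrual_deviance(s, 2)   # 2 * (2 + log(2) - 2 * log(2))
accrual_deviance <- function(series, rates) {
  series <- as_accrual_series(series)
  if (length(rates) == 1 && is.null(names(rates))) {
    lam <- rep(as.numeric(rates), nrow(series))
  } else {
    idx <- match(as.character(series$season), names(rates))
    if (anyNA(idx)) abort("`rates` must be named with every season present in the series.")
    lam <- as.numeric(rates)[idx]
  }
  if (any(lam < 0) || any(lam <= 0 & series$count > 0)) {
    abort("Rates must be positive wherever counts are positive (deviance would be infinite).")
  }
  -2 * sum(dpois(series$count, lam * series$duration, log = TRUE))
}

#' Per-season sufficient statistics for fast deviance evaluation
#' @noRd
deviance_stats <- function(series) {
  ss <- season_sets(series)
  const <- vapply(ss$quarters, function(idx) {
    sum(series$count[idx] * log(series$duration[idx])) -
      sum(lfactorial(series$count[idx]))
  }, numeric(1))
  list(m = ss$total_count, t = ss$total_duration, const = const,
       season = as.character(ss$season))
}

#' Deviance for a matrix of rate draws (rows = draws, cols = seasons or 1)
#' @noRd
deviance_draws <- function(stats, lam) {
  # -2 * sum_s [ M_s log(lambda_s) - lambda_s T_s + const_s ]
  if (ncol(lam) == 1) {
    m <- sum(stats$m); t <- sum(stats$t); k <- sum(stats$const)
    drop(-2 * (m * log(lam) - lam * t + k))
  } else {
    contrib <- sweep(log(lam), 2, stats$m, "*") - sweep(lam, 2, stats$t, "*")
    -2 * (rowSums(contrib) + sum(stats$const))
  }
}

#' Deviance Information Criterion of a fitted accrual model
#'
#' DIC = Dbar + pD with Dbar the posterior mean deviance (estimated from
#' posterior rate draws) and pD = Dbar - D(posterior mean), the classic
#' effective-parameter count with the posterior mean as the plug-in.
#' Lower DIC indicates a better fit/complexity trade-off.
#'
#' @param fit An [fit_accrual()] result carrying its series.
#' @param draws Number of posterior draws for Dbar (default 10000).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `model`, `dbar`, `d_at_mean`, `p_d`, `dic`,
#'   `draws`.
#' @export
#' @examples
#' s <- generate_series(c(summer = 9, fall = 6, winter = 3, spring = 5),
#'                      n_quarters = 24, seed = 7)
#' compute_dic(fit_accrual(s, gamma_prior(6.25, 0.5)), draws = 2000, seed = 1)
compute_dic <- function(fit, draws = 10000, seed = NULL) {
  stopifnot(inherits(fit, "accrual_fit"))
  if (is.null(fit$series)) abort("DIC needs a fit with observed data.")
  check_scalar_number(draws, "draws", 1)
  stats <- deviance_stats(fit$series)
  post <- fit$posterior

  if (fit$model == "homogeneous") {
    lam <- sample_rate_matrix(fit, draws, seed)
    post_mean <- matrix(post$shape / post$rate, nrow = 1)
  } else {
    lam_full <- sample_rate_matrix(fit, draws, seed)
    # align draw columns with the season order of the sufficient statistics
    lam <- lam_full[, stats$season, drop = FALSE]
    post_mean <- matrix(
      (post$shape / post$rate)[match(stats$season, as.character(post$season))],
      nrow = 1
    )
    # seasons with no observed quarters contribute nothing to the deviance
    empty <- stats$m == 0 & stats$t == 0
    if (any(empty)) {
      lam <- lam[, !empty, drop = FALSE]
      post_mean <- post_mean[, !empty, drop = FALSE]
      stats <- lapply(stats, function(x) x[!empty])
    }
  }

  dbar <- mean(deviance_draws(stats, lam))
  d_at_mean <- deviance_draws(stats, post_mean)
  tibble::tibble(
    model = fit$model,
    dbar = dbar,
    d_at_mean = d_at_mean,
    p_d = dbar - d_at_mean,
    dic = dbar + (dbar - d_at_mean),
    draws = as.integer(draws)
  )
}

#' Rolling internal prediction of total accrual
#'
#' For each origin `k = 1..J`, the model is refit on quarters `1..k` and the
#' remaining quarters `k+1..J` are predicted with [predict_total()]; each of
#' the `replicates` predicted totals \eqn{\hat M^r} (observed through k plus
#' simulated remainder) is compared against the actual total
#' \eqn{M_{true} = \sum_{j=1}^J m_j}. Reported per k:
#' \eqn{RMSE = \sqrt{\frac1R\sum_r (\hat M^r - M_{true})^2}},
#' \eqn{Bias = \frac1R\sum_r (\hat M^r - M_{true})} and the sample SD of the
#' \eqn{\hat M^r} (denominator R-1). Each k runs on an independent substream
#' derived from `seed`.
#'
#' @param series The full observed `accrual_series`.
#' @param prior A [gamma_prior()].
#' @param model `"homogeneous"` or `"seasonal"`. At small k a season may have
#'   no observed quarters yet; its predictions then use the unmodified prior.
#' @param replicates Predictive replicates per origin (at least 2).
#' @param seed Optional master integer seed.
#' @param scheme Predictive simulation scheme, see [predict_total()].
#' @return A tibble of class `accrual_evaluation`: one row per k with
#'   `model`, `k`, `rmse`, `bias`, `sd`, `m_true`, `replicates`.
#' @export
#' @examples
#' s <- generate_series(c(summer = 9, fall = 6, winter = 3, spring = 5),
#'                      n_quarters = 12, seed = 7)
#' rolling_evaluation(s, gamma_prior(6.25, 0.5), "homogeneous",
#'                    replicates = 500, seed = 1)
rolling_evaluation <- function(series, prior, model = c("homogeneous", "seasonal"),
                               replicates = 10000, seed = NULL,
                               scheme = c("shared", "per_quarter")) {
  series <- as_accrual_series(series)
  model <- match.arg(model)
  scheme <- match.arg(scheme)
  check_scalar_number(replicates, "replicates", 2)
  J <- nrow(series)
  m_true <- sum(series$count)
  sub_seeds <- derive_seeds(seed, J)

  rows <- purrr::map_dfr(seq_len(J), function(k) {
    sub <- accrual_series(
      count = series$count[1:k],
      season = series$season[1:k],
      duration = series$duration[1:k]
    )
    fit_k <- fit_accrual(sub, prior, model)
    future <- tibble::tibble(
      season = series$season[seq_len(J - k) + k],
      duration = series$duration[seq_len(J - k) + k]
    )
    pred <- predict_total(
      fit_k, future_quarters = future,
      observed_total = sum(series$count[1:k]),
      replicates = replicates, seed = sub_seeds[[k]], scheme = scheme
    )
    err <- pred$totals - m_true
    tibble::tibble(
      model = model,
      k = k,
      rmse = sqrt(mean(err^2)),
      bias = mean(err),
      sd = stats::sd(pred$totals),
      m_true = m_true,
      replicates = as.integer(replicates)
    )
  })
  class(rows) <- c("accrual_evaluation", class(rows))
  rows
}

#' @exportS3Method ggplot2::autoplot
autoplot.accrual_evaluation <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("rmse", "bias", "sd"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, levels = c("rmse", "bias", "sd"),
                        labels = c("RMSE", "Bias", "SD"))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$k, y = .data$value, colour = .data$model)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Observed quarters (k)", y = NULL, colour = "Model") +
    ggplot2::theme_minimal()
}
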