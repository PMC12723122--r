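#' Fit a gamma-Poisson accrual model
#'
#' Counts are modelled as \eqn{m_j \sim Poisson(\lambda_{S(j)} t_j)} where
#' \eqn{t_j} is the quarter's duration. Under the homogeneous model a single
#' rate \eqn{\lambda} applies to every quarter; under the seasonal model each
#' of the four seasons has its own rate, each with an independent copy of the
#' same gamma prior. Both posteriors are conjugate and computed exactly:
#' shape gains the summed counts and rate gains the summed exposure (overall,
#' or within each season). Seasons with no observed quarters retain the
#' unmodified prior.
#'
#' @param series An `accrual_series` (or data frame coercible to one). `NULL`
#'   yields a prior-only fit.
#' @param prior A [gamma_prior()].
#' @param model `"homogeneous"` (one shared rate) or `"seasonal"` (one rate
#'   per season).
#' @return An object of class `accrual_fit`: access the posterior
#'   shape/rate table with [tidy()] and fit-level metadata with [glance()].
#' @export
#' @examples
#' trial <- accrual_series(count = c(rep(5, 13), rep(6, 13)), season = "summer")
#' fit_accrual(trial, gamma_prior(6.25, 0.5), model = "homogeneous")
fit_accrual <- function(series, prior, model = c("homogeneous", "seasonal")) {
  model <- match.arg(model)
  if (!inherits(prior, "gamma_prior")) abort("`prior` must be a `gamma_prior`.")
  if (!is.null(series)) series <- as_accrual_series(series)

  if (model == "homogeneous") {
    m <- if (is.null(series)) 0 else sum(series$count)
    t <- if (is.null(series)) 0 else sum(series$duration)
    post <- tibble::tibble(
      season = season_factor(NA_character_),
      shape = prior$shape + m,
      rate = prior$rate + t,
      n_quarters = if (is.null(series)) 0L else nrow(series),
      total_count = m,
      total_duration = t
    )
  } else {
    ss <- if (is.null(series)) {
      tibble::tibble(
        season = season_factor(seasons()), n_quarters = 0L,
        total_count = 0, total_duration = 0
      )
    } else {
      season_sets(series)
    }
    post <- tibble::tibble(
      season = ss$season,
      shape = prior$shape + ss$total_count,
      rate = prior$rate + ss$total_duration,
      n_quarters = ss$n_quarters,
      total_count = ss$total_count,
      total_duration = ss$total_duration
    )
  }

  structure(
    list(model = model, prior = prior, posterior = post, series = series),
    class = "accrual_fit"
  )
}

#' @export
print.accrual_fit <- function(x, ...) {
  cat(sprintf(
    "<accrual_fit> %s gamma-Poisson model (prior shape %g, rate %g)\n",
    x$model, x$prior$shape, x$prior$rate
  ))
  print(posterior_summary(x))
  invisible(x)
}

#' Posterior summaries of accrual rates
#'
#' Posterior mean and equal-tailed credible interval for each rate in the
#' fit. The analytic method uses the exact gamma mean and inverse-CDF
#' quantiles; the Monte-Carlo method uses the sample mean and empirical
#' quantiles of `draws` posterior samples (useful for matching
#' simulation-based summaries).
#'
#' @param fit An `accrual_fit`.
#' @param level Credible level in (0, 1). Default 0.95.
#' @param method `"analytic"` (exact) or `"monte_carlo"`.
#' @param draws Number of posterior draws when `method = "monte_carlo"`.
#' @param seed Optional integer seed for the Monte-Carlo method.
#' @return A tibble with one row per rate: `season` (NA for the homogeneous
#'   model), `shape`, `rate`, `mean`, `lower`, `upper`, `prior_only`.
#' @export
#' @examples
#' fit <- fit_accrual(NULL, gamma_prior(145.25, 26.5))
#' posterior_summary(fit)
posterior_summary <- function(fit, level = 0.95,
                              method = c("analytic", "monte_carlo"),
                              draws = 10000, seed = NULL) {
  stopifnot(inherits(fit, "accrual_fit"))
  method <- match.arg(method)
  check_scalar_number(level, "level", 0, 1, open_lower = TRUE, open_upper = TRUE)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  post <- fit$posterior
  if (method == "analytic") {
    est <- post$shape / post$rate
    lo <- qgamma(probs[1], post$shape, rate = post$rate)
    hi <- qgamma(probs[2], post$shape, rate = post$rate)
  } else {
    check_scalar_number(draws, "draws", 1)
    sims <- sample_rate_matrix(fit, draws, seed)
    est <- colMeans(sims)
    qs <- apply(sims, 2, quantile, probs = probs, names = FALSE)
    lo <- qs[1, ]
    hi <- qs[2, ]
  }
  tibble::tibble(
    season = post$season,
    shape = post$shape,
    rate = post$rate,
    mean = est,
    lower = lo,
    upper = hi,
    prior_only = post$n_quarters == 0L
  )
}

#' Matrix of joint posterior rate draws (rows = draws, one column per rate)
#' @noRd
sample_rate_matrix <- function(fit, draws, seed = NULL) {
  post <- fit$posterior
  with_seed_opt(seed, {
    m <- vapply(
      seq_len(nrow(post)),
      function(i) rgamma(draws, post$shape[i], rate = post$rate[i]),
      numeric(draws)
    )
    matrix(m, nrow = draws,
           dimnames = list(NULL, as.character(post$season)))
  })
}

#' Draw samples from the posterior of the accrual rate(s)
#'
#' Direct i.i.d. conjugate sampling from the exact gamma posterior (the
#' posterior is available in closed form, so no Markov chain or burn-in is
#' involved).
#'
#' @inheritParams posterior_summary
#' @param draws Number of draws (at least 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `draw`, `season` (NA for the homogeneous
#'   model) and `rate`, in long format.
#' @export
#' @examples
#' fit <- fit_accrual(NULL, gamma_prior(6.25, 0.5))
#' sample_rate(fit, draws = 5, seed = 1)
sample_rate <- function(fit, draws = 10000, seed = NULL) {
  stopifnot(inherits(fit, "accrual_fit"))
  check_scalar_number(draws, "draws", 1)
  m <- sample_rate_matrix(fit, draws, seed)
  tibble::tibble(
    draw = rep(seq_len(nrow(m)), times = ncol(m)),
    season = season_factor(rep(
      as.character(fit$posterior$season), each = nrow(m)
    )),
    rate = as.vector(m)
  )
}

#' @exportS3Method generics::tidy
tidy.accrual_fit <- function(x, level = 0.95, ...) {
  out <- posterior_summary(x, level = level, ...)
  dplyr::rename(out, estimate = "mean", conf.low = "lower", conf.high = "upper")
}

#' @exportS3Method generics::glance
glance.accrual_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_rates = nrow(x$posterior),
    n_quarters = if (is.null(x$series)) 0L else nrow(x$series),
    total_count = if (is.null(x$series)) 0L else sum(x$series$count),
    total_exposure = if (is.null(x$series)) 0 else sum(x$series$duration),
    excluded_count = if (is.null(x$series)) 0L else
      attr(x$series, "excluded_count") %||% 0L,
    prior_shape = x$prior$shape,
    prior_rate = x$prior$rate
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.accrual_fit <- function(object, level = 0.999, n = 512, ...) {
  post <- object$posterior
  grid <- purrr::map_dfr(seq_len(nrow(post)), function(i) {
    xs <- seq(
      qgamma((1 - level) / 2, post$shape[i], rate = post$rate[i]),
      qgamma(1 - (1 - level) / 2, post$shape[i], rate = post$rate[i]),
      length.out = n
    )
    tibble::tibble(
      season = post$season[i],
      rate_value = xs,
      density = stats::dgamma(xs, post$shape[i], rate = post$rate[i])
    )
  })
  p <- ggplot2::ggplot(
    grid,
    ggplot2::aes(x = .data$rate_value, y = .data$density)
  ) +
    ggplot2::labs(
      x = "Accrual rate (participants/quarter)", y = "Posterior density"
    ) +
    ggplot2::theme_minimal()
  if (object$model == "seasonal") {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$season)) +
      ggplot2::labs(colour = "Season")
  } else {
    p + ggplot2::geom_line()
  }
}
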