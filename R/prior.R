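#' Gamma prior for a quarterly accrual rate
#'
#' The accrual rate \eqn{\lambda} (participants per full quarter) carries a
#' Gamma(shape, rate) prior with density proportional to
#' \eqn{\lambda^{shape-1} e^{-rate\,\lambda}}. Note the RATE
#' parameterization: `rate` multiplies \eqn{\lambda} in the exponent, so the
#' prior mean is `shape / rate` and `rate` is interpretable as quarters of
#' prior pseudo-exposure.
#'
#' @param shape Positive shape parameter.
#' @param rate Positive rate parameter.
#' @param confidence_p Optional elicitation weight in (0, 1] recorded for
#'   provenance (see [elicit_prior()]).
#' @return An object of class `gamma_prior`.
#' @export
#' @examples
#' gamma_prior(shape = 6.25, rate = 0.5)
gamma_prior <- function(shape, rate, confidence_p = NULL) {
  check_scalar_number(shape, "shape", 0, open_lower = TRUE)
  check_scalar_number(rate, "rate", 0, open_lower = TRUE)
  if (!is.null(confidence_p)) {
    check_scalar_number(confidence_p, "confidence_p", 0, 1, open_lower = TRUE)
  }
  structure(
    list(shape = shape, rate = rate, confidence_p = confidence_p),
    class = "gamma_prior"
  )
}

#' @export
print.gamma_prior <- function(x, ...) {
  cat(sprintf(
    "<gamma_prior> shape = %g, rate = %g (mean %.4g participants/quarter)\n",
    x$shape, x$rate, x$shape / x$rate
  ))
  if (!is.null(x$confidence_p)) {
    cat(sprintf("  elicited with confidence level p = %g\n", x$confidence_p))
  }
  invisible(x)
}

#' Elicit an accrual-rate prior from the trial plan
#'
#' Converts planned enrollment into a gamma prior: the planned per-quarter
#' rate is `target_enrollment / planned_quarters`, and the confidence level
#' `p` scales both hyperparameters, giving `shape = rate_planned * p` and
#' `rate = 1 * p`. The prior mean is then exactly the planned rate, while `p`
#' acts as the number of quarters of pseudo-exposure the prior is worth
#' (p = 1 counts as one fully observed quarter at the planned rate).
#'
#' The shape is returned unrounded; pass an explicit [gamma_prior()] to use
#' rounded published values.
#'
#' @param target_enrollment Planned total enrollment (positive).
#' @param planned_quarters Planned trial duration in quarters (positive).
#' @param confidence_p Prior confidence level in (0, 1].
#' @return A `gamma_prior`.
#' @export
#' @examples
#' elicit_prior(200, 16, 0.5)    # shape 6.25, rate 0.5
#' elicit_prior(1094, 16, 0.5)   # shape 34.184375, rate 0.5
elicit_prior <- function(target_enrollment, planned_quarters, confidence_p) {
  check_scalar_number(target_enrollment, "target_enrollment", 0, open_lower = TRUE)
  check_scalar_number(planned_quarters, "planned_quarters", 0, open_lower = TRUE)
  check_scalar_number(confidence_p, "confidence_p", 0, 1, open_lower = TRUE)
  gamma_prior(
    shape = target_enrollment / planned_quarters * confidence_p,
    rate = 1 * confidence_p,
    confidence_p = confidence_p
  )
}
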