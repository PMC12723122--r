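# Internal helpers shared across modules.

#' Evaluate an expression under an optional seed
#'
#' When `seed` is `NULL` the expression runs against the current RNG state;
#' otherwise the state is set locally and restored afterwards.
#' @noRd
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

#' Derive independent sub-seeds from a master seed
#'
#' Used wherever one call drives several stochastic stages (e.g. the rolling
#' evaluation, one sub-seed per origin k) so the stages never share a stream
#' yet the whole run is reproducible from the master seed alone.
#' @noRd
derive_seeds <- function(seed, n) {
  if (is.null(seed)) {
    return(rep(list(NULL), n))
  }
  as.list(with_seed_opt(seed, sample.int(.Machine$integer.max - 1L, n)))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must lie in %s%s, %s%s (got %s).",
      name,
      if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]",
      format(x)
    ))
  }
  invisible(x)
}
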