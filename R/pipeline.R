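#' Assemble a pipeline configuration
#'
#' Collects every knob of an end-to-end analysis with documented defaults.
#' The fully resolved configuration is echoed into the run record so any run
#' can be reproduced from its output alone.
#'
#' @param input Path to a delimited accrual table, or a data frame (an
#'   `accrual_series`, a quarterly table, or monthly records).
#' @param layout Input layout passed to [read_accrual_table()].
#' @param prior Either a [gamma_prior()], or a list with
#'   `target_enrollment`, `planned_quarters` and `confidence_p` for
#'   [elicit_prior()].
#' @param model `"homogeneous"`, `"seasonal"` or `"both"`.
#' @param horizon_q Optional prediction horizon in total quarters; `NULL`
#'   skips prediction.
#' @param replicates Simulation replicates for prediction/comparison/DIC.
#' @param seed Master integer seed; stage sub-seeds are derived from it.
#' @param level Credible level for all intervals.
#' @param scheme Predictive simulation scheme ([predict_total()]).
#' @param evaluate Run the rolling internal-prediction evaluation?
#' @param eval_replicates Replicates per rolling-evaluation origin.
#' @param calendar A [season_calendar()].
#' @param trial_start,drop_partial_first,partial_threshold,full_first_quarter
#'   Monthly-aggregation policies passed to [quarterize()].
#' @param trial_label Optional trial label.
#' @param observed_total Override for the enrollment total added to
#'   predictions (default: series total plus any excluded participants).
#' @param export_histogram Include the full predictive histogram in the run
#'   record?
#' @return A list of class `accrual_config`.
#' @export
accrual_config <- function(input, layout = "auto", prior,
                           model = c("both", "homogeneous", "seasonal"),
                           horizon_q = NULL, replicates = 10000, seed = NULL,
                           level = 0.95, scheme = "shared",
                           evaluate = FALSE, eval_replicates = 1000,
                           calendar = season_calendar(),
                           trial_start = NULL, drop_partial_first = TRUE,
                           partial_threshold = 0.5, full_first_quarter = TRUE,
                           trial_label = NULL, observed_total = NULL,
                           export_histogram = FALSE) {
  model <- match.arg(model)
  structure(
    list(
      input = input, layout = layout, prior = prior, model = model,
      horizon_q = horizon_q, replicates = replicates, seed = seed,
      level = level, scheme = scheme, evaluate = evaluate,
      eval_replicates = eval_replicates, calendar = calendar,
      trial_start = trial_start, drop_partial_first = drop_partial_first,
      partial_threshold = partial_threshold,
      full_first_quarter = full_first_quarter,
      trial_label = trial_label, observed_total = observed_total,
      export_histogram = export_histogram
    ),
    class = "accrual_config"
  )
}

resolve_prior <- function(prior) {
  if (inherits(prior, "gamma_prior")) return(prior)
  if (is.list(prior) && all(c("shape", "rate") %in% names(prior))) {
    return(gamma_prior(prior$shape, prior$rate, prior$confidence_p %||% NULL))
  }
  if (is.list(prior) &&
      all(c("target_enrollment", "planned_quarters", "confidence_p") %in% names(prior))) {
    return(elicit_prior(prior$target_enrollment, prior$planned_quarters,
                        prior$confidence_p))
  }
  abort(paste(
    "`prior` must be a gamma_prior, a list(shape, rate), or a",
    "list(target_enrollment, planned_quarters, confidence_p)."
  ))
}

#' Run the accrual-analysis pipeline
#'
#' Executes read -> (quarterize) -> prior -> fit -> predict -> seasonal
#' comparison -> DIC -> optional rolling evaluation, per the configuration,
#' and returns one structured, JSON-serialisable run record containing the
#' resolved configuration, the seed, and every result table. Stages log
#' progress to standard error when `verbose = TRUE`.
#'
#' @param config An [accrual_config()].
#' @param output_dir Optional directory; when given, the run record is
#'   written as `run_record.json` and the summary tables as CSV files.
#' @param verbose Log stage progress to standard error?
#' @return A list of class `accrual_run` with elements `config`, `series`,
#'   `prior`, and per-model `fits`, `summaries`, `predictions`,
#'   `comparison`, `dic`, `evaluation`.
#' @export
#' @examples
#' s <- generate_series(c(summer = 7, fall = 6, winter = 4, spring = 5),
#'                      n_quarters = 16, seed = 3)
#' cfg <- accrual_config(s, prior = gamma_prior(6.25, 0.5),
#'                       model = "both", horizon_q = 24,
#'                       replicates = 2000, seed = 11)
#' run <- run_pipeline(cfg, verbose = FALSE)
#' run$summaries$seasonal
run_pipeline <- function(config, output_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "accrual_config"))
  say <- function(...) if (verbose) message("[bayesaccrual] ", sprintf(...))

  # --- read / aggregate ------------------------------------------------
  input <- config$input
  if (is.character(input)) {
    say("reading %s", input)
    input <- read_accrual_table(input, layout = config$layout,
                                calendar = config$calendar,
                                trial_label = config$trial_label)
  }
  if (is.data.frame(input) && "month_start" %in% names(input)) {
    say("aggregating %d monthly records into seasonal quarters", nrow(input))
    series <- quarterize(
      input, trial_start = config$trial_start,
      drop_partial_first = config$drop_partial_first,
      partial_threshold = config$partial_threshold,
      full_first_quarter = config$full_first_quarter,
      calendar = config$calendar, trial_label = config$trial_label
    )
    exc <- attr(series, "excluded_count")
    if (exc > 0) {
      warn(sprintf(
        "Dropped a partial first quarter; %d participant(s) excluded from modeling (still counted in predictive totals).",
        exc
      ))
    }
  } else {
    series <- as_accrual_series(input, trial_label = config$trial_label,
                                calendar = config$calendar)
  }

  prior <- resolve_prior(config$prior)
  models <- if (config$model == "both") c("homogeneous", "seasonal") else config$model
  stage_seeds <- derive_seeds(config$seed, 4L * length(models))
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    stage_seeds[[si]]
  }

  fits <- summaries <- predictions <- dics <- evaluations <- list()
  comparison <- NULL

  for (m in models) {
    say("fitting %s model", m)
    fit <- fit_accrual(series, prior, model = m)
    fits[[m]] <- fit
    smry <- posterior_summary(fit, level = config$level)
    if (m == "seasonal" && any(smry$prior_only)) {
      warn(sprintf(
        "Season(s) with no observed quarters retain the prior: %s.",
        paste(smry$season[smry$prior_only], collapse = ", ")
      ))
    }
    summaries[[m]] <- smry

    pred_seed <- next_seed()
    if (!is.null(config$horizon_q)) {
      say("predicting total accrual through quarter %d", config$horizon_q)
      predictions[[m]] <- predict_total(
        fit, horizon_q = config$horizon_q,
        observed_total = config$observed_total,
        replicates = config$replicates, seed = pred_seed,
        scheme = config$scheme, level = config$level
      )
    }

    cmp_seed <- next_seed()
    if (m == "seasonal") {
      say("comparing seasonal rates")
      comparison <- compare_seasons(fit, draws = config$replicates,
                                    seed = cmp_seed)
    }

    dic_seed <- next_seed()
    if (length(models) > 1) {
      dics[[m]] <- compute_dic(fit, draws = config$replicates, seed = dic_seed)
    }

    eval_seed <- next_seed()
    if (isTRUE(config$evaluate)) {
      say("rolling internal prediction (%s, %d origins)", m, nrow(series))
      evaluations[[m]] <- rolling_evaluation(
        series, prior, model = m,
        replicates = config$eval_replicates, seed = eval_seed,
        scheme = config$scheme
      )
    }
  }

  run <- structure(
    list(
      config = config,
      package_version = as.character(utils::packageVersion("bayesaccrual")),
      series = series,
      prior = prior,
      fits = fits,
      summaries = summaries,
      predictions = predictions,
      comparison = comparison,
      dic = if (length(dics)) dplyr::bind_rows(dics) else NULL,
      evaluation = if (length(evaluations)) dplyr::bind_rows(evaluations) else NULL
    ),
    class = "accrual_run"
  )

  if (!is.null(output_dir)) {
    write_run_record(run, output_dir)
    say("wrote results under %s", output_dir)
  }
  run
}

#' Serialize a run record to JSON and CSV under a directory
#' @noRd
write_run_record <- function(run, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- run$config
  record <- list(
    schema = "bayesaccrual/run-record/v1",
    package_version = run$package_version,
    config = list(
      layout = cfg$layout, model = cfg$model, horizon_q = cfg$horizon_q,
      replicates = cfg$replicates, seed = cfg$seed, level = cfg$level,
      scheme = cfg$scheme, evaluate = cfg$evaluate,
      eval_replicates = cfg$eval_replicates,
      drop_partial_first = cfg$drop_partial_first,
      partial_threshold = cfg$partial_threshold,
      full_first_quarter = cfg$full_first_quarter,
      trial_label = cfg$trial_label
    ),
    prior = list(shape = run$prior$shape, rate = run$prior$rate,
                 confidence_p = run$prior$confidence_p),
    series = list(
      n_quarters = nrow(run$series),
      total_count = sum(run$series$count),
      excluded_count = attr(run$series, "excluded_count") %||% 0L
    ),
    posterior = lapply(run$summaries, as.data.frame),
    predictions = lapply(run$predictions, function(p) {
      g <- as.list(glance(p))
      if (isTRUE(cfg$export_histogram)) {
        g$histogram <- as.data.frame(summarize_predictive(p)$histogram)
      }
      g
    }),
    comparison = if (!is.null(run$comparison)) {
      list(
        pairwise = as.data.frame(tidy(run$comparison)),
        extreme = as.data.frame(run$comparison$extreme)
      )
    },
    dic = if (!is.null(run$dic)) as.data.frame(run$dic),
    evaluation = if (!is.null(run$evaluation)) as.data.frame(run$evaluation)
  )
  jsonlite::write_json(record, file.path(output_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  write_accrual_table(run$series, file.path(output_dir, "series.csv"))
  for (m in names(run$summaries)) {
    readr::write_csv(run$summaries[[m]],
                     file.path(output_dir, sprintf("posterior_%s.csv", m)),
                     progress = FALSE)
  }
  if (!is.null(run$evaluation)) {
    readr::write_csv(run$evaluation, file.path(output_dir, "evaluation.csv"),
                     progress = FALSE)
  }
  if (!is.null(run$dic)) {
    readr::write_csv(run$dic, file.path(output_dir, "dic.csv"),
                     progress = FALSE)
  }
  invisible(output_dir)
}

#' @export
print.accrual_run <- function(x, ...) {
  cat("<accrual_run>\n")
  print(x$series)
  for (m in names(x$summaries)) {
    cat(sprintf("\n-- %s model --\n", m))
    print(x$summaries[[m]])
    if (!is.null(x$predictions[[m]])) print(x$predictions[[m]])
  }
  if (!is.null(x$comparison)) print(x$comparison)
  if (!is.null(x$dic)) {
    cat("\n-- DIC --\n")
    print(x$dic)
  }
  invisible(x)
}
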