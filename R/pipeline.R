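#' Run the full trajectory-analysis pipeline
#'
#' Orchestrates simulate (optional) -> preprocess -> class-number selection
#' -> archetype labeling -> outcome tabulation -> logistic regression ->
#' no-medication sensitivity analysis, with all randomness flowing from the
#' configuration's master seed. Identical configuration yields an identical
#' report.
#'
#' @param config A `steptraj_config` for the synthetic generator, or `NULL`
#'   when `steps` and `checkups` are supplied directly.
#' @param steps,checkups Raw input tables (see [preprocess_steps()]); used
#'   when `config` is `NULL`.
#' @param g_range,min_class_share,min_mean_posterior See [select_G()].
#' @param flat_tolerance See [label_archetype()].
#' @param n_starts See [fit_lcmm()].
#' @param seed Seed for model fitting when `config` is `NULL` (otherwise
#'   `config$seed` is used).
#' @param out_dir Optional directory; when given, all stage artifacts
#'   (weekly series, cohort, search table, posterior, labels, outcome and
#'   odds-ratio tables, JSON run report) are written there.
#' @param quiet Suppress progress messages.
#' @return A `steptraj_run` report list: exclusion counts, the search
#'   table, chosen `G`, labels, outcome table, odds-ratio tables (main and
#'   sensitivity), and the fitted objects.
#' @export
run_pipeline <- function(config = default_config(), steps = NULL,
                         checkups = NULL, g_range = 1:5,
                         min_class_share = 0.05, min_mean_posterior = 0.90,
                         flat_tolerance = 0.10, n_starts = 3, seed = 1L,
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (is.null(config) && (is.null(steps) || is.null(checkups))) {
    abort("either `config` or both `steps` and `checkups` must be given",
          class = "steptraj_config_error")
  }
  if (!is.null(config)) {
    say("simulating population (n = ", config$n_participants, ")")
    pop <- generate_population(config)
    steps <- pop$steps
    checkups <- pop$checkups
    seed <- config$seed
  } else {
    pop <- NULL
  }

  say("preprocessing")
  prep <- preprocess_steps(steps, checkups)

  say("selecting number of classes over G in {",
      paste(g_range, collapse = ", "), "}")
  sel <- select_G(prep$weekly, g_range = g_range,
                  min_class_share = min_class_share,
                  min_mean_posterior = min_mean_posterior,
                  n_starts = n_starts, seed = seed)
  fit <- sel$best
  labels <- label_classes(fit, flat_tolerance = flat_tolerance)

  cohort <- prep$cohort %>%
    left_join(select(fit$assignment, "participant_id", "class"),
              by = "participant_id") %>%
    left_join(select(labels, "class", "archetype"), by = "class") %>%
    mutate(outcome = weight_loss_flag(.data$pre_weight, .data$post_weight))

  say("outcome analysis")
  outcome_table <- summarize_outcomes(cohort)
  main_fit <- fit_logistic(cohort)
  sens_fit <- tryCatch(sensitivity_no_medication(cohort),
                       error = function(e) {
                         say("sensitivity analysis skipped: ",
                             conditionMessage(e))
                         NULL
                       })

  report <- structure(
    list(n_input = prep$n_input,
         n_cohort = prep$n_output,
         exclusions = prep$exclusions,
         records_removed = prep$records_removed,
         search = sel$search,
         G = sel$G,
         labels = labels,
         outcome_table = outcome_table,
         or_table = main_fit$table,
         or_table_sensitivity = if (!is.null(sens_fit)) sens_fit$table,
         fit = fit,
         selection = sel,
         main_fit = main_fit,
         sensitivity_fit = sens_fit,
         cohort = cohort,
         weekly = prep$weekly,
         population = pop,
         seed = seed),
    class = "steptraj_run"
  )
  if (!is.null(out_dir)) write_run(report, out_dir)
  report
}

#' @export
print.steptraj_run <- function(x, ...) {
  cat("steptraj pipeline run\n")
  cat(sprintf("  cohort: %d of %d participants retained\n",
              x$n_cohort, x$n_input))
  cat(sprintf("  selected G = %d; archetypes: %s\n", x$G,
              paste(x$labels$archetype, collapse = ", ")))
  cat("  outcome by class:\n")
  print(as.data.frame(x$outcome_table), row.names = FALSE)
  cat("  adjusted odds ratios:\n")
  print(as.data.frame(x$or_table), digits = 3, row.names = FALSE)
  invisible(x)
}

# write every stage artifact of a run as delimited text / JSON
write_run <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(report$weekly, file.path(out_dir, "weekly_series.csv"))
  readr::write_csv(report$cohort, file.path(out_dir, "cohort.csv"))
  readr::write_csv(report$search, file.path(out_dir, "class_search.csv"))
  readr::write_csv(report$labels, file.path(out_dir, "class_labels.csv"))
  readr::write_csv(report$outcome_table,
                   file.path(out_dir, "outcome_by_class.csv"))
  readr::write_csv(report$or_table, file.path(out_dir, "odds_ratios.csv"))
  if (!is.null(report$or_table_sensitivity)) {
    readr::write_csv(report$or_table_sensitivity,
                     file.path(out_dir, "odds_ratios_no_medication.csv"))
  }
  write_lcmm_fit(report$fit, out_dir)
  meta <- list(
    n_input = report$n_input, n_cohort = report$n_cohort,
    exclusions = report$exclusions, records_removed = report$records_removed,
    G = report$G, seed = report$seed
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
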