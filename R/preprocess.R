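#' Resolve same-day dual-device records
#'
#' When a participant's steps were reported by both platforms on the same
#' day, only the larger value is kept; single-source days pass unchanged.
#'
#' @param steps Tibble of daily records with columns `participant_id`,
#'   `date`, `source`, `steps`.
#' @return A tibble with exactly one record per participant-day.
#' @export
#' @examples
#' x <- tibble::tibble(participant_id = "a", date = Sys.Date(),
#'                     source = c("ios", "android"), steps = c(5000, 6000))
#' resolve_device_duplicates(x)$steps
resolve_device_duplicates <- function(steps) {
  steps %>%
    group_by(.data$participant_id, .data$date) %>%
    arrange(dplyr::desc(.data$steps), .data$source, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup()
}

#' Remove out-of-range daily step values
#'
#' Drops implausible device days: strictly fewer than `lo` or strictly more
#' than `hi` steps (the bounds themselves are retained). The defaults,
#' 200 and 50,000 steps/day, are the conventional plausibility cut-offs for
#' smartphone step data.
#'
#' @param steps Tibble of (deduplicated) daily records.
#' @param lo,hi Inclusive plausibility bounds in steps/day.
#' @return The filtered tibble.
#' @export
filter_daily_range <- function(steps, lo = 200, hi = 50000) {
  if (lo >= hi) abort("`lo` must be smaller than `hi`",
                      class = "steptraj_config_error")
  filter(steps, .data$steps >= lo, .data$steps <= hi)
}

#' Select each participant's eligible checkup pair
#'
#' For each participant the first checkup is paired with a later checkup
#' whose interval lies within 10-14 calendar months; among qualifying
#' pairs the one whose interval is closest to 12 months is chosen
#' (ties broken toward the earlier second checkup). Participants without a
#' qualifying pair are dropped. Month arithmetic is calendar-based with the
#' day-of-month clamped to the month end.
#'
#' @param checkups Tibble with columns `participant_id`, `date`,
#'   `weight_kg`, `bmi`, `age`, `sex`, `smoking`, `medication`.
#' @param window Eligible interval in months (inclusive).
#' @param target_months The interval the chosen pair should be nearest to.
#' @return One row per retained participant: `participant_id`,
#'   `first_date`, `second_date`, `interval_days`, `pre_weight`,
#'   `post_weight`, `pre_bmi`, `post_bmi`, and the first-checkup covariates
#'   `age`, `sex`, `smoking`, `medication`.
#' @export
select_shc_pair <- function(checkups, window = c(10, 14), target_months = 12) {
  pick_one <- function(d) {
    d <- arrange(d, .data$date)
    if (nrow(d) < 2L) return(NULL)
    first <- d[1L, ]
    later <- d[-1L, ]
    lo <- add_months(first$date, window[1])
    hi <- add_months(first$date, window[2])
    ok <- later$date >= lo & later$date <= hi
    if (!any(ok)) return(NULL)
    cand <- later[ok, ]
    target <- add_months(first$date, target_months)
    dist <- abs(as.numeric(cand$date - target))
    second <- cand[order(dist, cand$date), ][1L, ]
    tibble(
      participant_id = first$participant_id,
      first_date = first$date,
      second_date = second$date,
      interval_days = as.integer(second$date - first$date),
      pre_weight = first$weight_kg, post_weight = second$weight_kg,
      pre_bmi = first$bmi, post_bmi = second$bmi,
      age = first$age, sex = first$sex,
      smoking = first$smoking, medication = first$medication
    )
  }
  checkups %>%
    dplyr::group_split(.data$participant_id) %>%
    purrr::map(pick_one) %>%
    bind_rows()
}

#' Exclude participants with outlying day-to-day variance
#'
#' Removes participants whose individual daily-step variance exceeds
#' `multiplier` times the pooled variance of all retained daily records.
#' With `multiplier = Inf` the filter is disabled.
#'
#' @param steps Tibble of filtered, deduplicated daily records.
#' @param multiplier Threshold multiplier on the pooled variance.
#' @return The daily records minus excluded participants; the excluded ids
#'   are attached as attribute `"excluded"`.
#' @export
exclude_high_variance <- function(steps, multiplier = 1) {
  if (nrow(steps) == 0L) {
    return(structure(steps, excluded = character()))
  }
  pooled <- var(steps$steps)
  v <- steps %>%
    group_by(.data$participant_id) %>%
    summarise(v = if (n() > 1L) var(.data$steps) else 0, .groups = "drop")
  bad <- v$participant_id[!is.na(v$v) & v$v > multiplier * pooled]
  out <- filter(steps, !.data$participant_id %in% bad)
  structure(out, excluded = bad)
}

#' Weekly average step counts between the two checkups
#'
#' Week `j` covers days `7(j-1)+1 ... 7j` after the first checkup (the
#' checkup day itself is excluded); the weekly value is the mean over the
#' available valid days of that week. Participants with any week in
#' `1..T` containing no valid day are excluded. `T` is the number of
#' started weeks in the checkup interval, capped at `max_weeks` (longer
#' series are truncated).
#'
#' @param steps Tibble of filtered, deduplicated daily records.
#' @param shc_pairs Output of [select_shc_pair()].
#' @param max_weeks Cap on the number of elapsed weeks.
#' @return A long tibble `participant_id`, `week`, `mean_steps` covering
#'   every week `1..T` for each retained participant; excluded ids are in
#'   attribute `"excluded"`.
#' @export
weekly_average <- function(steps, shc_pairs, max_weeks = 56L) {
  if (any(shc_pairs$interval_days <= 0)) {
    abort("second checkup date must be after the first",
          class = "steptraj_input_error")
  }
  joined <- steps %>%
    dplyr::inner_join(select(shc_pairs, "participant_id", "first_date",
                             "interval_days"),
                      by = "participant_id") %>%
    mutate(offset = as.integer(.data$date - .data$first_date)) %>%
    filter(.data$offset >= 1L, .data$offset <= .data$interval_days) %>%
    mutate(week = (.data$offset + 6L) %/% 7L,
           T_i = pmin((.data$interval_days + 6L) %/% 7L,
                      as.integer(max_weeks))) %>%
    filter(.data$week <= .data$T_i)

  weekly <- joined %>%
    group_by(.data$participant_id, .data$week) %>%
    summarise(mean_steps = mean(.data$steps), T_i = .data$T_i[1L],
              .groups = "drop")

  complete <- weekly %>%
    group_by(.data$participant_id) %>%
    summarise(ok = n_distinct(.data$week) == .data$T_i[1L], .groups = "drop")
  keep <- complete$participant_id[complete$ok]
  excluded <- setdiff(shc_pairs$participant_id, keep)

  out <- weekly %>%
    filter(.data$participant_id %in% keep) %>%
    select("participant_id", "week", "mean_steps") %>%
    arrange(.data$participant_id, .data$week)
  structure(out, excluded = excluded)
}

#' Assemble the analysis-ready cohort
#'
#' Joins the weekly series with the checkup pairs and applies the
#' eligibility filters: pre-checkup BMI of at least `min_bmi` (25 kg/m^2,
#' the overweight threshold) and age within `age_range` (the 40-74 year
#' checkup-eligible band); both boundaries are inclusive.
#'
#' @param weekly Weekly series from [weekly_average()].
#' @param shc_pairs Checkup pairs from [select_shc_pair()]; every
#'   participant in `weekly` must appear here.
#' @param min_bmi Minimum (inclusive) pre-checkup BMI.
#' @param age_range Inclusive age bounds in years.
#' @return A cohort tibble: `participant_id`, `elapsed_weeks`,
#'   `mean_steps`, `mean_steps_k`, weights, BMI and covariates. Per-filter
#'   exclusion counts are attached as attribute `"exclusions"`.
#' @export
build_cohort <- function(weekly, shc_pairs, min_bmi = 25,
                         age_range = c(40, 74)) {
  ids <- unique(weekly$participant_id)
  missing_pair <- setdiff(ids, shc_pairs$participant_id)
  if (length(missing_pair)) {
    abort(paste0("participants without a checkup pair in `shc_pairs`: ",
                 paste(head(missing_pair, 5), collapse = ", ")),
          class = "steptraj_consistency_error")
  }
  series_stats <- if (nrow(weekly) == 0L) {
    tibble(participant_id = character(), elapsed_weeks = integer(),
           mean_steps = numeric())
  } else {
    weekly %>%
      group_by(.data$participant_id) %>%
      summarise(elapsed_weeks = max(.data$week),
                mean_steps = mean(.data$mean_steps), .groups = "drop")
  }
  full <- shc_pairs %>%
    filter(.data$participant_id %in% ids) %>%
    left_join(series_stats, by = "participant_id") %>%
    mutate(mean_steps_k = .data$mean_steps / 1000)

  low_bmi <- full$pre_bmi < min_bmi
  bad_age <- !low_bmi & (full$age < age_range[1] | full$age > age_range[2])
  cohort <- full[!low_bmi & !bad_age, ] %>%
    select("participant_id", "elapsed_weeks", "mean_steps", "mean_steps_k",
           "pre_weight", "post_weight", "pre_bmi", "post_bmi",
           "age", "sex", "smoking", "medication",
           "first_date", "second_date")
  structure(cohort,
            exclusions = tibble(stage = c("low_bmi", "age_out_of_range"),
                                n_excluded = c(sum(low_bmi), sum(bad_age))))
}

#' Full preprocessing pipeline
#'
#' Applies, in order: checkup-pair selection, dual-device deduplication,
#' daily range filtering, the high-variance participant filter, weekly
#' averaging with the complete-weeks rule, and cohort eligibility, while
#' counting exclusions at each stage (the flowchart surrogate).
#'
#' @inheritParams filter_daily_range
#' @inheritParams select_shc_pair
#' @param checkups Raw checkup records, see [select_shc_pair()].
#' @param variance_multiplier See [exclude_high_variance()].
#' @param max_weeks See [weekly_average()].
#' @param min_bmi,age_range See [build_cohort()].
#' @return A `steptraj_preprocessed` list: `weekly` (long weekly series),
#'   `cohort`, `pairs`, `exclusions` (participant-level counts by stage),
#'   `records_removed` (record-level counts), `n_input`, `n_output`.
#' @export
preprocess_steps <- function(steps, checkups, lo = 200, hi = 50000,
                             variance_multiplier = 1, max_weeks = 56L,
                             min_bmi = 25, age_range = c(40, 74),
                             window = c(10, 14), target_months = 12) {
  all_ids <- union(unique(steps$participant_id),
                   unique(checkups$participant_id))
  pairs <- select_shc_pair(checkups, window = window,
                           target_months = target_months)
  n_no_pair <- length(setdiff(all_ids, pairs$participant_id))

  dedup <- resolve_device_duplicates(steps)
  n_dupes <- nrow(steps) - nrow(dedup)
  ranged <- filter_daily_range(dedup, lo = lo, hi = hi)
  n_out_of_range <- nrow(dedup) - nrow(ranged)
  varfilt <- exclude_high_variance(ranged, multiplier = variance_multiplier)
  high_var_ids <- attr(varfilt, "excluded")
  high_var_ids <- intersect(high_var_ids, pairs$participant_id)

  pairs_kept <- filter(pairs, !.data$participant_id %in% high_var_ids)
  weekly <- weekly_average(varfilt, pairs_kept, max_weeks = max_weeks)
  n_empty_week <- length(attr(weekly, "excluded"))

  cohort <- build_cohort(weekly, pairs_kept, min_bmi = min_bmi,
                         age_range = age_range)
  weekly_final <- semi_join(weekly, cohort, by = "participant_id")

  exclusions <- bind_rows(
    tibble(stage = "no_shc_pair", n_excluded = n_no_pair),
    tibble(stage = "high_variance", n_excluded = length(high_var_ids)),
    tibble(stage = "empty_week", n_excluded = n_empty_week),
    attr(cohort, "exclusions")
  )
  structure(
    list(weekly = weekly_final,
         cohort = cohort,
         pairs = pairs_kept,
         exclusions = exclusions,
         records_removed = tibble(
           stage = c("device_duplicates", "out_of_range"),
           n_removed = c(n_dupes, n_out_of_range)),
         n_input = length(all_ids),
         n_output = nrow(cohort)),
    class = "steptraj_preprocessed"
  )
}

#' @export
print.steptraj_preprocessed <- function(x, ...) {
  cat("Preprocessed step cohort:", x$n_output, "of", x$n_input,
      "participants retained\n")
  cat("Participant exclusions by stage:\n")
  for (i in seq_len(nrow(x$exclusions))) {
    cat(sprintf("  %-18s %d\n", x$exclusions$stage[i],
                x$exclusions$n_excluded[i]))
  }
  cat(sprintf("Records removed: %d duplicates, %d out-of-range days\n",
              x$records_removed$n_removed[1], x$records_removed$n_removed[2]))
  invisible(x)
}
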