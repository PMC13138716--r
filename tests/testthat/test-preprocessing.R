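# Preprocessing: deduplication, range filter, checkup pairing, weekly
# averaging, variance filter, cohort eligibility.

mk_steps <- function(...) {
  tibble::tibble(...)
}

test_that("dual-device days keep the larger value", {
  d0 <- as.Date("2021-06-01")
  x <- mk_steps(participant_id = c("a", "a", "a", "b", "b"),
                date = c(d0, d0, d0 + 1, d0, d0),
                source = c("ios", "android", "ios", "ios", "android"),
                steps = c(5000, 6000, 4000, 7000, 7000))
  out <- resolve_device_duplicates(x)
  expect_equal(nrow(out), 3)
  expect_equal(out$steps[out$participant_id == "a" & out$date == d0], 6000)
  expect_equal(out$steps[out$participant_id == "a" & out$date == d0 + 1],
               4000)
  expect_equal(out$steps[out$participant_id == "b"], 7000)
})

test_that("daily range filter is strict outside and inclusive at bounds", {
  x <- mk_steps(participant_id = "a",
                date = as.Date("2021-06-01") + 0:4,
                source = "ios",
                steps = c(199, 200, 25000, 50000, 50001))
  out <- filter_daily_range(x)
  expect_equal(out$steps, c(200, 25000, 50000))
  expect_error(filter_daily_range(x, lo = 300, hi = 300),
               class = "steptraj_config_error")
})

test_that("checkup pairing follows the 10-14 month window, nearest 12", {
  mk_shc <- function(id, dates) {
    tibble::tibble(participant_id = id, date = as.Date(dates),
                   weight_kg = 80, bmi = 27, age = 60, sex = 1,
                   smoking = 0, medication = 0)
  }
  # two candidates: 11.8 months beats 13.5 months
  shc <- mk_shc("a", c("2021-04-01", "2022-03-25", "2022-05-16"))
  out <- select_shc_pair(shc)
  expect_equal(out$second_date, as.Date("2022-03-25"))
  # single pair exactly 12 months
  shc <- mk_shc("b", c("2021-04-01", "2022-04-01"))
  expect_equal(select_shc_pair(shc)$second_date, as.Date("2022-04-01"))
  # 9-month follow-up only: excluded
  shc <- mk_shc("c", c("2021-04-01", "2022-01-01"))
  expect_equal(nrow(select_shc_pair(shc)), 0)
  # 15-month follow-up only: excluded
  shc <- mk_shc("d", c("2021-04-01", "2022-07-02"))
  expect_equal(nrow(select_shc_pair(shc)), 0)
  # window boundaries are inclusive (exactly 10 and 14 calendar months)
  shc <- mk_shc("e", c("2021-04-01", "2022-02-01"))
  expect_equal(nrow(select_shc_pair(shc)), 1)
  shc <- mk_shc("f", c("2021-04-01", "2022-06-01"))
  expect_equal(nrow(select_shc_pair(shc)), 1)
  # fewer than two checkups: excluded
  shc <- mk_shc("g", "2021-04-01")
  expect_equal(nrow(select_shc_pair(shc)), 0)
})

test_that("weekly averages cover started weeks and enforce completeness", {
  d0 <- as.Date("2021-04-01")
  pairs <- tibble::tibble(participant_id = c("a", "b"),
                          first_date = d0, second_date = d0 + 21,
                          interval_days = 21L,
                          pre_weight = 80, post_weight = 78, pre_bmi = 27,
                          post_bmi = 26.5, age = 60, sex = 1, smoking = 0,
                          medication = 0)
  # a: full weeks; b: week 2 entirely missing
  steps <- dplyr::bind_rows(
    mk_steps(participant_id = "a", date = d0 + 1:21, source = "ios",
             steps = rep(7000, 21)),
    mk_steps(participant_id = "b", date = d0 + c(1:7, 15:21),
             source = "ios", steps = 7000)
  )
  wk <- weekly_average(steps, pairs)
  expect_equal(unique(wk$participant_id), "a")
  expect_equal(wk$mean_steps, rep(7000, 3))
  expect_equal(attr(wk, "excluded"), "b")
  # mean over available days only
  steps2 <- mk_steps(participant_id = "a", date = d0 + c(2, 5, 8:14, 15:21),
                     source = "ios",
                     steps = c(6000, 8000, rep(7000, 14)))
  wk2 <- weekly_average(steps2, pairs[1, ])
  expect_equal(wk2$mean_steps[wk2$week == 1], 7000)
  # invalid interval
  bad <- pairs[1, ]
  bad$interval_days <- -3L
  expect_error(weekly_average(steps, bad), class = "steptraj_input_error")
})

test_that("series longer than the cap are truncated, not dropped", {
  d0 <- as.Date("2021-04-01")
  pairs <- tibble::tibble(participant_id = "a", first_date = d0,
                          second_date = d0 + 70, interval_days = 70L,
                          pre_weight = 80, post_weight = 78, pre_bmi = 27,
                          post_bmi = 26.5, age = 60, sex = 1, smoking = 0,
                          medication = 0)
  steps <- mk_steps(participant_id = "a", date = d0 + 1:70, source = "ios",
                    steps = 7000)
  wk <- weekly_average(steps, pairs, max_weeks = 8)
  expect_equal(max(wk$week), 8)
})

test_that("high-variance participants are excluded against pooled variance", {
  d0 <- as.Date("2021-04-01")
  flat <- dplyr::bind_rows(lapply(1:6, function(i) {
    mk_steps(participant_id = paste0("f", i), date = d0 + 1:20,
             source = "ios", steps = 7000)
  }))
  wild <- mk_steps(participant_id = "w", date = d0 + 1:20, source = "ios",
                   steps = rep(c(200, 50000), 10))
  out <- exclude_high_variance(dplyr::bind_rows(flat, wild))
  expect_equal(attr(out, "excluded"), "w")
  expect_false("w" %in% out$participant_id)
  # identical constant series: nobody excluded
  out2 <- exclude_high_variance(flat)
  expect_length(attr(out2, "excluded"), 0)
  # infinite multiplier disables the filter
  out3 <- exclude_high_variance(dplyr::bind_rows(flat, wild),
                                multiplier = Inf)
  expect_equal(nrow(out3), nrow(flat) + nrow(wild))
})

test_that("cohort eligibility boundaries are inclusive", {
  d0 <- as.Date("2021-04-01")
  mk_pair <- function(id, bmi, age) {
    tibble::tibble(participant_id = id, first_date = d0,
                   second_date = d0 + 364, interval_days = 364L,
                   pre_weight = 80, post_weight = 77, pre_bmi = bmi,
                   post_bmi = bmi, age = age, sex = 1, smoking = 0,
                   medication = 0)
  }
  pairs <- dplyr::bind_rows(mk_pair("a", 24.9, 60), mk_pair("b", 25.0, 40),
                            mk_pair("c", 27, 74), mk_pair("d", 27, 75))
  weekly <- tidyr::crossing(participant_id = c("a", "b", "c", "d"),
                            week = 1:52) %>%
    dplyr::mutate(mean_steps = 7000)
  cohort <- build_cohort(weekly, pairs)
  expect_setequal(cohort$participant_id, c("b", "c"))
  exc <- attr(cohort, "exclusions")
  expect_equal(exc$n_excluded[exc$stage == "low_bmi"], 1)
  expect_equal(exc$n_excluded[exc$stage == "age_out_of_range"], 1)
  expect_equal(cohort$mean_steps, rep(7000, 2))
  expect_equal(cohort$elapsed_weeks, rep(52, 2))
  # participant with a series but no checkup pair is a consistency error
  expect_error(build_cohort(weekly, pairs[1:3, ]),
               class = "steptraj_consistency_error")
  # empty input gives an empty cohort with zero exclusion counts
  empty <- build_cohort(weekly[0, ], pairs[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(sum(attr(empty, "exclusions")$n_excluded), 0)
})

test_that("record filters are idempotent and counts add up", {
  cfg <- default_config(n_participants = 60, n_weeks = 6, seed = 17)
  pop <- generate_population(cfg)
  once <- filter_daily_range(resolve_device_duplicates(pop$steps))
  twice <- filter_daily_range(resolve_device_duplicates(once))
  expect_equal(as.data.frame(once), as.data.frame(twice))
  expect_lte(nrow(once), nrow(pop$steps))
  prep <- preprocess_steps(pop$steps, pop$checkups, window = c(0, 14))
  expect_equal(prep$n_input - prep$n_output,
               sum(prep$exclusions$n_excluded))
})

test_that("range filter removes exactly the injected artifact days", {
  # curves high and noise small enough that genuine days stay in range
  curves <- rbind(A = c(8000, 10, 0), B = c(10000, -5, 0))
  cfg <- default_config(n_participants = 40, n_weeks = 8, seed = 23,
                        class_shares = c(A = 0.5, B = 0.5),
                        class_curves = curves,
                        random_intercept_sd = 500, daily_noise_sd = 600,
                        missing_day_prob = 0.1,
                        artifact_probs = c(low = 0.05, high = 0.03),
                        dual_device_prob = 0,
                        outcome_model = list(
                          intercept = qlogis(0.25),
                          class_logodds = c(A = 0, B = 0.5),
                          age = 0, age_center = 65, sex = 0, smoking = 0,
                          medication = 0, steps_per_k = 0,
                          steps_center_k = 5.8))
  pop <- generate_population(cfg)
  expect_gt(nrow(pop$artifacts), 0)
  dedup <- resolve_device_duplicates(pop$steps)
  kept <- filter_daily_range(dedup)
  removed <- dplyr::anti_join(dedup, kept,
                              by = c("participant_id", "date"))
  expect_setequal(paste(removed$participant_id, removed$date),
                  paste(pop$artifacts$participant_id, pop$artifacts$date))
})
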