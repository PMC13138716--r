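#' Default synthetic cohort configuration
#'
#' Builds the configuration for [generate_population()]. The default emulates
#' the study conditions of a roughly one-year mobile-health step cohort of
#' adults with BMI >= 25: four latent trajectory archetypes (DOWN, UP/DOWN,
#' FLAT, UP) whose quadratic mean curves are calibrated so that the curve
#' averages over weeks 1-28 and 29-52 match the reference per-period class
#' means (DOWN 8024 -> 6278, UP/DOWN 7347 -> 7763, FLAT 5243 -> 5270,
#' UP 6469 -> 8894 steps/day), class shares 355/193/2045/185 out of 2778,
#' a between-person random intercept, day-level Gaussian noise, missing
#' days, out-of-range artifact days, occasional same-day dual-device
#' duplicates, and a binary >= 3 percent weight-loss outcome whose log-odds
#' depend on class and covariates.
#'
#' @param n_participants Number of participants to simulate.
#' @param n_weeks Number of elapsed weeks between the two health checkups
#'   (the second checkup falls `7 * n_weeks` days after the first).
#' @param seed Master integer seed; every participant draws from a substream
#'   derived deterministically from it.
#' @param class_shares Named probability vector over archetypes (sums to 1).
#' @param class_curves Numeric matrix, one row per archetype, columns
#'   `(beta0, beta1, beta2)` of the quadratic mean curve
#'   `beta0 + beta1 * t + beta2 * t^2` in steps/day on the elapsed-week scale.
#' @param random_intercept_sd Between-person intercept SD (steps/day).
#' @param daily_noise_sd Day-to-day noise SD (steps/day).
#' @param missing_day_prob Probability that a day's record is never synced.
#' @param artifact_probs Named probabilities `c(low = , high = )` that a
#'   recorded day is replaced by an artifact in `[0, 199]` or
#'   `[50001, 80000]` steps.
#' @param dual_device_prob Probability that a recorded day also emits a
#'   lower secondary record from the participant's other platform.
#' @param outcome_model List of logistic coefficients for the >= 3 percent
#'   weight-loss outcome: `intercept`, per-class `class_logodds` (aligned
#'   with the archetypes), `age` (per year, centred at `age_center`), `sex`,
#'   `smoking`, `medication`, `steps_per_k` (per 1000 steps/day, centred at
#'   `steps_center_k`).
#' @param covariate_distributions List describing the covariate marginals:
#'   truncated-normal age (years) and BMI (kg/m^2, left-truncated so the
#'   default cohort is checkup-eligible), normal pre-weight (kg), and
#'   Bernoulli sex/smoking/medication.
#' @param start_date Date of every participant's first checkup.
#'
#' @return A `steptraj_config` list understood by [generate_population()].
#' @seealso [generate_population()]
#' @export
#' @examples
#' cfg <- default_config(n_participants = 50, seed = 7)
#' sum(cfg$class_shares)
default_config <- function(n_participants = 500L,
                           n_weeks = 52L,
                           seed = 1L,
                           class_shares = c(DOWN = 355, UP_DOWN = 193,
                                            FLAT = 2045, UP = 185) / 2778,
                           class_curves = NULL,
                           random_intercept_sd = 2000,
                           daily_noise_sd = 2500,
                           missing_day_prob = 0.15,
                           artifact_probs = c(low = 0.005, high = 0.002),
                           dual_device_prob = 0.05,
                           outcome_model = NULL,
                           covariate_distributions = NULL,
                           start_date = as.Date("2021-04-01")) {
  if (is.null(class_curves)) {
    class_curves <- rbind(
      DOWN    = calibrate_curve(8023.8, 6278.0),
      UP_DOWN = calibrate_curve(7347.1, 7763.0, vertex = 30),
      FLAT    = calibrate_curve(5243.2, 5270.2),
      UP      = calibrate_curve(6469.0, 8894.1)
    )
    colnames(class_curves) <- c("beta0", "beta1", "beta2")
  }
  if (is.null(outcome_model)) {
    # class effects are log-odds offsets from FLAT chosen so the marginal
    # class-conditional outcome rates sit near 21.1/24.4/22.3/41.1 percent
    outcome_model <- list(
      intercept = qlogis(0.223),
      class_logodds = c(DOWN    = qlogis(0.211) - qlogis(0.223),
                        UP_DOWN = qlogis(0.244) - qlogis(0.223),
                        FLAT    = 0,
                        UP      = qlogis(0.411) - qlogis(0.223)),
      age = -0.01, age_center = 65,
      sex = 0.10, smoking = 0.10, medication = -0.10,
      steps_per_k = log(1.01), steps_center_k = 5.822
    )
  }
  if (is.null(covariate_distributions)) {
    covariate_distributions <- list(
      age_mean = 65.0, age_sd = 8.1, age_range = c(40, 74),
      p_male = 0.576, p_smoking = 0.075, p_medication = 0.638,
      weight_mean = 72.1, weight_sd = 9.8, weight_min = 40,
      bmi_mean = 27.2, bmi_sd = 2.3, bmi_min = 25
    )
  }
  cfg <- structure(
    list(n_participants = as.integer(n_participants),
         n_weeks = as.integer(n_weeks),
         seed = as.integer(seed),
         class_shares = class_shares,
         class_curves = class_curves,
         random_intercept_sd = random_intercept_sd,
         daily_noise_sd = daily_noise_sd,
         missing_day_prob = missing_day_prob,
         artifact_probs = artifact_probs,
         dual_device_prob = dual_device_prob,
         outcome_model = outcome_model,
         covariate_distributions = covariate_distributions,
         start_date = start_date),
    class = "steptraj_config"
  )
  validate_config(cfg)
  cfg
}

# Solve for quadratic coefficients whose averages over weeks 1..split and
# (split+1)..weeks hit the two target per-period means. Linear classes fix
# beta2 = 0; a rise-then-fall class instead fixes the vertex week.
calibrate_curve <- function(mean1, mean2, weeks = 52L, split = 28L,
                            vertex = NULL) {
  w1 <- seq_len(split)
  w2 <- seq.int(split + 1L, weeks)
  if (is.null(vertex)) {
    A <- rbind(c(1, mean(w1)), c(1, mean(w2)))
    b <- solve(A, c(mean1, mean2))
    c(b[1], b[2], 0)
  } else {
    # beta1 = -2 * vertex * beta2 places the turning point at `vertex`
    A <- rbind(c(1, mean(w1) * (-2 * vertex) + mean(w1^2)),
               c(1, mean(w2) * (-2 * vertex) + mean(w2^2)))
    b <- solve(A, c(mean1, mean2))
    c(b[1], -2 * vertex * b[2], b[2])
  }
}

validate_config <- function(config) {
  if (!inherits(config, "steptraj_config")) {
    abort("`config` must be built by `default_config()`.")
  }
  num <- c(config$class_shares, config$class_curves,
           config$random_intercept_sd, config$daily_noise_sd,
           config$missing_day_prob, config$artifact_probs,
           config$dual_device_prob,
           unlist(config$outcome_model),
           unlist(config$covariate_distributions))
  if (!all(is.finite(num))) {
    abort("configuration contains non-finite values", class = "steptraj_config_error")
  }
  shares <- config$class_shares
  if (any(shares < 0) || abs(sum(shares) - 1) > 1e-12) {
    abort("`class_shares` must be non-negative and sum to 1 within 1e-12",
          class = "steptraj_config_error")
  }
  G <- length(shares)
  if (!is.matrix(config$class_curves) || nrow(config$class_curves) != G) {
    abort("`class_curves` must be a matrix with one row per class share",
          class = "steptraj_config_error")
  }
  if (length(config$outcome_model$class_logodds) != G) {
    abort("`outcome_model$class_logodds` must have one entry per class",
          class = "steptraj_config_error")
  }
  if (config$n_weeks < 2) {
    abort("`n_weeks` must be at least 2", class = "steptraj_config_error")
  }
  if (config$random_intercept_sd < 0 || config$daily_noise_sd < 0) {
    abort("standard deviations must be non-negative",
          class = "steptraj_config_error")
  }
  probs <- c(config$missing_day_prob, config$artifact_probs,
             config$dual_device_prob)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]", class = "steptraj_config_error")
  }
  invisible(config)
}

#' Simulate a step-count cohort with known latent structure
#'
#' Generates raw daily step records, paired health-checkup records, and the
#' ground truth behind them, so that every downstream stage (preprocessing,
#' model fitting, class-number selection, outcome regression) can be tested
#' against a known answer. Per participant: a latent class is drawn from the
#' configured shares, a random intercept from
#' `N(0, random_intercept_sd^2)`, and each day's steps are
#' `round(curve(week) + intercept + noise)` floored at zero; days are then
#' dropped at the missing rate, replaced by out-of-range artifacts at the
#' artifact rates, and occasionally doubled by a lower same-day record from
#' the participant's other platform. The two checkups fall `7 * n_weeks`
#' days apart; the binary >= 3 percent weight-loss outcome is drawn from
#' the configured logistic model, and the post-checkup weight is back-filled
#' from the drawn outcome (relative loss in `[3%, 12%]` when positive,
#' `(-10%, 3%)` otherwise).
#'
#' Identical configuration (including seed) yields identical output, and
#' each participant has their own deterministic substream, so the first
#' `k` participants of a larger run coincide with a run of size `k`.
#'
#' @param config A `steptraj_config`, see [default_config()].
#'
#' @return A `steptraj_population` list with tibbles:
#' \describe{
#'   \item{steps}{`participant_id`, `date`, `source`, `steps` — raw daily
#'     device records (possibly several per day).}
#'   \item{checkups}{two rows per participant: `participant_id`, `date`,
#'     `weight_kg`, `bmi`, `age`, `sex`, `smoking`, `medication`.}
#'   \item{truth}{per participant: latent `class` index, `archetype` name,
#'     random `intercept`, `outcome_prob`, drawn `outcome`, and the latent
#'     mean step level `mean_steps_true`.}
#'   \item{artifacts}{the injected out-of-range days
#'     (`participant_id`, `date`, `kind`).}
#' }
#' @export
#' @examples
#' pop <- generate_population(default_config(n_participants = 20, n_weeks = 4))
#' dplyr::count(pop$truth, archetype)
generate_population <- function(config) {
  validate_config(config)
  withr::local_preserve_seed()

  G <- length(config$class_shares)
  archetypes <- names(config$class_shares)
  if (is.null(archetypes)) archetypes <- paste0("class", seq_len(G))
  n <- config$n_participants
  n_days <- config$n_weeks * 7L
  week_of_day <- rep(seq_len(config$n_weeks), each = 7L)
  curve_vals <- sapply(seq_len(config$n_weeks), function(w) {
    config$class_curves[, 1] + config$class_curves[, 2] * w +
      config$class_curves[, 3] * w^2
  })
  curve_vals <- matrix(curve_vals, nrow = G)  # G x n_weeks
  cv <- config$covariate_distributions
  om <- config$outcome_model
  dates <- config$start_date + seq_len(n_days)

  steps_list <- vector("list", n)
  truth_list <- vector("list", n)
  checkup_list <- vector("list", n)
  artifact_list <- vector("list", n)

  rtruncnorm1 <- function(mean, sd, lo = -Inf, hi = Inf) {
    u <- runif(1, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
    qnorm(u, mean, sd)
  }

  for (i in seq_len(n)) {
    set.seed(sub_seed(config$seed, i))
    id <- sprintf("P%05d", i)
    g <- sample.int(G, 1L, prob = config$class_shares)
    u <- rnorm(1, 0, config$random_intercept_sd)

    age <- round(rtruncnorm1(cv$age_mean, cv$age_sd,
                             cv$age_range[1], cv$age_range[2]))
    sex <- as.integer(runif(1) < cv$p_male)
    smoking <- as.integer(runif(1) < cv$p_smoking)
    medication <- as.integer(runif(1) < cv$p_medication)
    pre_weight <- max(cv$weight_min, rnorm(1, cv$weight_mean, cv$weight_sd))
    bmi <- rtruncnorm1(cv$bmi_mean, cv$bmi_sd, lo = cv$bmi_min)
    primary <- if (runif(1) < 0.5) "ios" else "android"
    secondary <- if (primary == "ios") "android" else "ios"

    steps <- pmax(0, round(curve_vals[g, week_of_day] + u +
                             rnorm(n_days, 0, config$daily_noise_sd)))
    kept <- runif(n_days) >= config$missing_day_prob
    a_low <- kept & runif(n_days) < config$artifact_probs[["low"]]
    a_high <- kept & !a_low & runif(n_days) < config$artifact_probs[["high"]]
    steps[a_low] <- floor(runif(sum(a_low), 0, 200))
    steps[a_high] <- floor(runif(sum(a_high), 50001, 80001))
    dual <- kept & runif(n_days) < config$dual_device_prob

    idx <- which(kept)
    rec <- tibble(participant_id = id, date = dates[idx],
                  source = primary, steps = as.numeric(steps[idx]))
    d_idx <- which(dual)
    if (length(d_idx)) {
      rec <- bind_rows(rec, tibble(
        participant_id = id, date = dates[d_idx], source = secondary,
        steps = pmax(0, round(steps[d_idx] * runif(length(d_idx), 0.5, 0.95)))
      ))
    }
    steps_list[[i]] <- rec
    if (any(a_low | a_high)) {
      artifact_list[[i]] <- tibble(
        participant_id = id,
        date = dates[a_low | a_high],
        kind = ifelse(a_low[a_low | a_high], "low", "high")
      )
    }

    mean_steps_true <- mean(curve_vals[g, ]) + u
    lin <- om$intercept + om$class_logodds[[g]] +
      om$age * (age - om$age_center) + om$sex * sex +
      om$smoking * smoking + om$medication * medication +
      om$steps_per_k * (mean_steps_true / 1000 - om$steps_center_k)
    p <- plogis(lin)
    y <- as.integer(runif(1) < p)
    loss <- if (y == 1L) runif(1, 0.03, 0.12) else runif(1, -0.10, 0.03)
    post_weight <- pre_weight * (1 - loss)

    truth_list[[i]] <- tibble(
      participant_id = id, class = g, archetype = archetypes[g],
      intercept = u, outcome_prob = p, outcome = y,
      mean_steps_true = mean_steps_true
    )
    checkup_list[[i]] <- tibble(
      participant_id = id,
      date = c(config$start_date, config$start_date + n_days),
      weight_kg = c(pre_weight, post_weight),
      bmi = c(bmi, bmi * post_weight / pre_weight),
      age = age, sex = sex, smoking = smoking, medication = medication
    )
  }

  structure(
    list(steps = bind_rows(steps_list),
         checkups = bind_rows(checkup_list),
         truth = bind_rows(truth_list),
         artifacts = if (length(artifact_list)) bind_rows(artifact_list) else
           tibble(participant_id = character(), date = as.Date(character()),
                  kind = character()),
         config = config),
    class = "steptraj_population"
  )
}

#' @export
print.steptraj_population <- function(x, ...) {
  cat("Synthetic step cohort:", nrow(x$truth), "participants,",
      nrow(x$steps), "daily records,",
      length(x$config$class_shares), "latent classes\n")
  invisible(x)
}

#' Write a synthetic population to delimited text files
#'
#' Writes the same schemas the preprocessing stage reads: a steps table
#' (`participant_id`, `date`, `source`, `steps`), a checkup table, and the
#' ground-truth table as separate CSV files.
#'
#' @param population A `steptraj_population` from [generate_population()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "steptraj_population"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("steps.csv", "checkups.csv", "truth.csv"))
  readr::write_csv(population$steps, paths[1])
  readr::write_csv(population$checkups, paths[2])
  readr::write_csv(population$truth, paths[3])
  invisible(paths)
}
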