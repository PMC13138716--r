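# Outcome definition, per-class tabulation, logistic regression.

test_that("weight-loss flag is inclusive at exactly 3 percent", {
  expect_equal(weight_loss_flag(100, 97.0), 1L)
  expect_equal(weight_loss_flag(100, 97.1), 0L)
  expect_equal(weight_loss_flag(76.9, 76.1), 0L)   # ~1.04% loss
  expect_equal(weight_loss_flag(c(80, 90), c(70, 89)), c(1L, 0L))
  expect_error(weight_loss_flag(0, 10), class = "steptraj_input_error")
})

test_that("per-class outcome table reproduces known percentages", {
  tab <- summarize_outcomes(table2_fixture())
  get <- function(cls, col) tab[[col]][tab$class == cls]
  expect_equal(get("Overall", "pct_loss"), 23.6)
  expect_equal(get("UP", "pct_loss"), 41.1)
  expect_equal(get("FLAT", "pct_loss"), 22.3)
  expect_equal(get("DOWN", "pct_loss"), 21.1)
  expect_equal(get("UP_DOWN", "pct_loss"), 24.4)
  expect_equal(get("Overall", "n"), 2778)
  # counts decompose: events + non-events = n
  expect_equal(tab$n - tab$n_loss >= 0, rep(TRUE, nrow(tab)))

  all_pos <- tibble::tibble(archetype = c("A", "A", "B"), outcome = 1L)
  expect_equal(summarize_outcomes(all_pos)$pct_loss, c(100, 100, 100))
  expect_error(summarize_outcomes(table2_fixture()[0, ]),
               class = "steptraj_input_error")
})

test_that("single binary predictor reproduces the cross-product OR", {
  # 2x2 table: a=30 exposed events, b=70 exposed non-events,
  #            c=15 unexposed events, d=185 unexposed non-events
  rows <- tibble::tibble(
    archetype = rep(c("UP", "FLAT"), c(100, 200)),
    outcome = c(rep(1L, 30), rep(0L, 70), rep(1L, 15), rep(0L, 185)))
  fit <- fit_logistic(rows, adjust = character())
  or <- fit$table$odds_ratio[fit$table$term == "UP"]
  expect_equal(or, (30 * 185) / (70 * 15), tolerance = 1e-8)
})

test_that("IRLS coefficients match an independent optimizer", {
  withr::local_seed(55)
  for (rep in 1:10) {
    n <- 80
    # age entered centred: keeps the likelihood well conditioned so the
    # two optimisers are comparable to full precision
    rows <- tibble::tibble(
      archetype = sample(c("FLAT", "UP"), n, replace = TRUE),
      age = rnorm(n, 0, 8), sex = rbinom(n, 1, 0.5),
      mean_steps_k = runif(n, 3, 9), smoking = rbinom(n, 1, 0.2),
      medication = rbinom(n, 1, 0.5))
    lin <- -0.5 + 0.8 * (rows$archetype == "UP") + 0.03 * rows$age
    rows$outcome <- rbinom(n, 1, plogis(lin))
    if (sum(rows$outcome) %in% c(0, n)) next
    fit <- tryCatch(fit_logistic(rows, adjust = c("age", "sex")),
                    error = function(e) NULL)
    if (is.null(fit)) next
    X <- cbind(1, rows$archetype == "UP", rows$age, rows$sex)
    y <- rows$outcome
    negll <- function(b) {
      eta <- X %*% b
      -sum(y * eta - log1p(exp(eta)))
    }
    grad <- function(b) -as.vector(t(X) %*% (y - plogis(X %*% b)))
    opt <- optim(rep(0, 4), negll, grad, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    opt <- stats::nlminb(opt$par, negll, grad,
                         control = list(rel.tol = 1e-15, x.tol = 1e-14,
                                        iter.max = 500))
    expect_lt(max(abs(fit$table$estimate - opt$par)), 1e-6)
  }
})

test_that("null data give odds ratios near one and row order is irrelevant", {
  rows <- simulate_outcome_rows(20000, up_logodds = 0, seed = 77)
  rows$outcome <- withr::with_seed(78, rbinom(nrow(rows), 1, 0.25))
  fit <- fit_logistic(rows)
  cls <- fit$table[fit$table$term %in% c("UP", "DOWN", "UP_DOWN"), ]
  expect_true(all(abs(cls$estimate) < 0.15))
  shuffled <- rows[withr::with_seed(79, sample(nrow(rows))), ]
  fit2 <- fit_logistic(shuffled)
  expect_equal(dplyr::arrange(fit$table, term),
               dplyr::arrange(fit2$table, term), tolerance = 1e-10)
})

test_that("Wald intervals use the normal quantile and exponentiate", {
  rows <- simulate_outcome_rows(3000, up_logodds = log(2.45), seed = 5)
  fit <- fit_logistic(rows)
  t <- fit$table
  expect_equal(t$odds_ratio, exp(t$estimate))
  expect_equal(t$ci_low, exp(t$estimate - 1.959964 * t$std_error),
               tolerance = 1e-6)
  expect_true(all(t$ci_low <= t$odds_ratio & t$odds_ratio <= t$ci_high))
  expect_equal(t$p_value, 2 * pnorm(-abs(t$estimate / t$std_error)))
})

test_that("degenerate outcome data are rejected with estimation errors", {
  rows <- tibble::tibble(archetype = c("UP", "FLAT"), outcome = c(1L, 1L),
                         age = 60, sex = 1, mean_steps_k = 6,
                         smoking = 0, medication = 0)
  expect_error(fit_logistic(rows), class = "steptraj_estimation_error")
})

test_that("no-medication sensitivity drops the term and subsets", {
  rows <- simulate_outcome_rows(4000, up_logodds = log(2), seed = 31)
  sens <- sensitivity_no_medication(rows)
  expect_equal(sens$n, sum(rows$medication == 0))
  expect_false("medication" %in% sens$table$term)
  # when nobody medicates, sensitivity equals the main fit minus the term
  rows0 <- rows
  rows0$medication <- 0L
  main <- suppressMessages(fit_logistic(rows0))
  sens0 <- sensitivity_no_medication(rows0)
  expect_equal(main$table, sens0$table, tolerance = 1e-10)
  rows1 <- rows
  rows1$medication <- 1L
  expect_error(sensitivity_no_medication(rows1),
               class = "steptraj_estimation_error")
})
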