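# The >= 3% weight-loss outcome and its logistic regression on trajectory
# class.

#' Binary weight-loss outcome
#'
#' Flags a relative weight loss of at least `threshold` between the two
#' checkups: `1` iff `(pre - post) / pre >= threshold` (inclusive).
#'
#' @param pre_weight,post_weight Weights in kg; vectorised.
#' @param threshold Relative loss defining the outcome (default 3%).
#' @return Integer vector of 0/1 flags.
#' @export
#' @examples
#' weight_loss_flag(100, 97)    # 1 (exactly 3%)
#' weight_loss_flag(100, 97.1)  # 0
weight_loss_flag <- function(pre_weight, post_weight, threshold = 0.03) {
  if (any(pre_weight <= 0)) abort("`pre_weight` must be positive",
                                  class = "steptraj_input_error")
  as.integer((pre_weight - post_weight) / pre_weight >= threshold)
}

#' Tabulate the outcome by trajectory class
#'
#' Counts and percentages (half-up rounded to one decimal) of the binary
#' outcome per class and overall.
#'
#' @param data Tibble with an `outcome` column (0/1) and a class label
#'   column (`archetype` if present, else `class`).
#' @return A tibble `class`, `n`, `n_loss`, `pct_loss` with an `"Overall"`
#'   row appended.
#' @export
summarize_outcomes <- function(data) {
  if (nrow(data) == 0L) abort("empty cohort", class = "steptraj_input_error")
  cls <- if ("archetype" %in% names(data)) "archetype" else "class"
  per <- data %>%
    group_by(class = as.character(.data[[cls]])) %>%
    summarise(n = n(), n_loss = sum(.data$outcome), .groups = "drop") %>%
    mutate(pct_loss = round_half_up(100 * .data$n_loss / .data$n, 1))
  overall <- tibble(class = "Overall", n = nrow(data),
                    n_loss = sum(data$outcome)) %>%
    mutate(pct_loss = round_half_up(100 * .data$n_loss / .data$n, 1))
  bind_rows(per, overall)
}

#' Logistic regression of the outcome on trajectory class
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares) of the binary >= 3% weight-loss outcome on the trajectory
#' class, dummy-coded with `FLAT` as the reference, adjusted for the
#' requested covariates. Mean step counts enter per 1000 steps/day
#' (`mean_steps_k`). Odds ratios are `exp(b)` with 95% Wald confidence
#' intervals `exp(b +/- 1.959964 se)` and Wald p-values from the standard
#' normal. Rows with missing model variables are dropped (complete-case).
#'
#' @param data Tibble with `outcome`, a class label column (`archetype` or
#'   `class`), and the adjustment covariates.
#' @param adjust Character vector of adjustment covariates; constant
#'   columns are dropped with a message.
#' @param reference Reference class label (default `"FLAT"`).
#' @param conf_level Confidence level for the Wald intervals.
#' @return A `steptraj_logit` object; `tidy()` returns the per-term table
#'   (`term`, `estimate`, `std_error`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`).
#' @export
fit_logistic <- function(data,
                         adjust = c("age", "sex", "mean_steps_k",
                                    "smoking", "medication"),
                         reference = "FLAT", conf_level = 0.95) {
  cls <- if ("archetype" %in% names(data)) "archetype" else "class"
  if (!"mean_steps_k" %in% names(data) && "mean_steps" %in% names(data)) {
    data$mean_steps_k <- data$mean_steps / 1000
  }
  missing_adj <- setdiff(adjust, names(data))
  if (length(missing_adj)) {
    abort(paste0("missing adjustment columns: ",
                 paste(missing_adj, collapse = ", ")),
          class = "steptraj_input_error")
  }
  keep <- stats::complete.cases(data[, c("outcome", cls, adjust)])
  data <- data[keep, ]
  if (sum(data$outcome) == 0L || sum(data$outcome) == nrow(data)) {
    abort("need at least one event and one non-event",
          class = "steptraj_estimation_error")
  }
  constant <- adjust[vapply(adjust, function(a)
    length(unique(data[[a]])) < 2L, logical(1))]
  if (length(constant)) {
    message("dropping constant adjustment term(s): ",
            paste(constant, collapse = ", "))
    adjust <- setdiff(adjust, constant)
  }
  lev <- unique(as.character(data[[cls]]))
  if (reference %in% lev) lev <- c(reference, setdiff(lev, reference))
  data$.class <- factor(as.character(data[[cls]]), levels = lev)

  rhs <- paste(c(if (length(lev) > 1) ".class", adjust), collapse = " + ")
  if (rhs == "") rhs <- "1"
  form <- as.formula(paste("outcome ~", rhs))

  separation <- FALSE
  model <- withCallingHandlers(
    glm(form, family = binomial(), data = data,
        control = list(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  b <- coef(model)
  se <- sqrt(diag(vcov(model)))
  if (separation || !model$converged || any(abs(b[-1]) > 15)) {
    worst <- names(which.max(abs(b[-1])))
    abort(paste0("logistic estimation failed (separation or non-convergence); ",
                 "offending term: ", worst),
          class = "steptraj_estimation_error")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  term <- sub("^\\.class", "", names(b))
  table <- tibble(
    term = term,
    estimate = unname(b),
    std_error = unname(se),
    odds_ratio = exp(unname(b)),
    ci_low = exp(unname(b) - z * unname(se)),
    ci_high = exp(unname(b) + z * unname(se)),
    p_value = 2 * pnorm(-abs(unname(b) / unname(se)))
  )
  structure(
    list(table = table, model = model, n = nrow(data),
         reference = reference, adjust = adjust,
         conf_level = conf_level, converged = model$converged),
    class = "steptraj_logit"
  )
}

#' @export
print.steptraj_logit <- function(x, ...) {
  cat(sprintf("Weight-loss logistic model (n = %d, reference class %s)\n",
              x$n, x$reference))
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @rdname fit_logistic
#' @param x,object A `steptraj_logit`.
#' @param ... Unused.
#' @export
tidy.steptraj_logit <- function(x, ...) x$table

#' @rdname fit_logistic
#' @export
glance.steptraj_logit <- function(x, ...) {
  tibble(n = x$n, loglik = as.numeric(stats::logLik(x$model)),
         aic = x$model$aic, converged = x$converged)
}

#' @rdname fit_logistic
#' @export
autoplot.steptraj_logit <- function(object, ...) {
  d <- filter(object$table, .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(.data$odds_ratio,
                                  stats::reorder(.data$term,
                                                 .data$odds_ratio))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Sensitivity analysis in the no-medication subset
#'
#' Refits the weight-loss logistic model on participants not taking
#' medication, with the medication term dropped.
#'
#' @inheritParams fit_logistic
#' @param ... Passed on to [fit_logistic()].
#' @return A `steptraj_logit`.
#' @export
sensitivity_no_medication <- function(data,
                                      adjust = c("age", "sex",
                                                 "mean_steps_k", "smoking"),
                                      ...) {
  if (!"medication" %in% names(data)) {
    abort("`medication` column required", class = "steptraj_input_error")
  }
  subset <- filter(data, .data$medication == 0)
  if (nrow(subset) == 0L) {
    abort("no participants without medication",
          class = "steptraj_estimation_error")
  }
  fit_logistic(subset, adjust = setdiff(adjust, "medication"), ...)
}
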