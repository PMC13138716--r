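# Class-number selection and archetype labeling.

#' Admissibility of a fitted class solution
#'
#' A fitted model is admissible when every class holds at least
#' `min_class_share` of the participants under modal assignment and the
#' mean posterior probability among each class's assigned members is at
#' least `min_mean_posterior`. An empty class (share 0) is inadmissible.
#'
#' @param fit A `steptraj_lcmm`.
#' @param min_class_share Minimum modal share per class (default 5%).
#' @param min_mean_posterior Minimum mean posterior per class
#'   (default 0.90).
#' @return `TRUE` or `FALSE`.
#' @export
admissible <- function(fit, min_class_share = 0.05,
                       min_mean_posterior = 0.90) {
  shares <- fit$class_counts / fit$N
  mp <- fit$mean_posterior
  all(shares >= min_class_share) &&
    !anyNA(mp) && all(mp >= min_mean_posterior)
}

# minimum-BIC admissible row; equal BIC broken toward smaller G
choose_admissible <- function(search) {
  ok <- which(search$admissible)
  if (!length(ok)) return(NA_integer_)
  ok[order(search$bic[ok], search$G[ok])][1L]
}

#' Choose the number of latent classes
#'
#' Fits the model for every `G` in `g_range` and selects, among admissible
#' fits (every class share at least `min_class_share`, every mean posterior
#' at least `min_mean_posterior`), the one with the minimum BIC; an exact
#' BIC tie is broken toward the smaller `G`. The full search table is
#' returned alongside the chosen fit.
#'
#' @inheritParams fit_lcmm
#' @inheritParams admissible
#' @param g_range Integer vector of class numbers to try.
#' @param ... Passed on to [fit_lcmm()].
#' @return A `steptraj_selection` list: `best` (the chosen fit), `G`
#'   (chosen class count), `search` (per-G table of loglik, BIC, minimum
#'   share, minimum mean posterior, admissibility), `fits` (all fits), and
#'   the criteria used. Errors with class `"steptraj_selection_error"`
#'   (carrying the search table) if no `G` is admissible.
#' @export
select_G <- function(weekly, g_range = 1:5, min_class_share = 0.05,
                     min_mean_posterior = 0.90, n_starts = 3, seed = 1L,
                     ...) {
  g_range <- sort(unique(as.integer(g_range)))
  fits <- vector("list", length(g_range))
  rows <- vector("list", length(g_range))
  for (k in seq_along(g_range)) {
    G <- g_range[k]
    fit <- fit_lcmm(weekly, G, n_starts = n_starts,
                    seed = sub_seed(seed, G), ...)
    fits[[k]] <- fit
    adm <- admissible(fit, min_class_share, min_mean_posterior)
    rows[[k]] <- tibble(
      G = G,
      loglik = fit$loglik,
      bic = fit$bic,
      min_share = min(fit$class_counts / fit$N),
      min_mean_posterior = suppressWarnings(min(fit$mean_posterior)),
      converged = fit$converged,
      admissible = adm
    )
  }
  search <- bind_rows(rows)
  idx <- choose_admissible(search)
  if (is.na(idx)) {
    abort("no class number in `g_range` met the admissibility conditions",
          class = "steptraj_selection_error", search = search)
  }
  structure(
    list(best = fits[[idx]], G = g_range[idx], search = search, fits = fits,
         criteria = list(min_class_share = min_class_share,
                         min_mean_posterior = min_mean_posterior)),
    class = "steptraj_selection"
  )
}

#' @export
print.steptraj_selection <- function(x, ...) {
  cat(sprintf("Class-number search: chose G = %d (share >= %.0f%%, mean posterior >= %.0f%%, min BIC)\n",
              x$G, 100 * x$criteria$min_class_share,
              100 * x$criteria$min_mean_posterior))
  print(as.data.frame(x$search), digits = 6, row.names = FALSE)
  invisible(x)
}

#' @rdname select_G
#' @param x,object A `steptraj_selection`.
#' @export
tidy.steptraj_selection <- function(x, ...) x$search

#' @rdname select_G
#' @export
autoplot.steptraj_selection <- function(object, ...) {
  ggplot2::ggplot(object$search,
                  ggplot2::aes(.data$G, .data$bic,
                               shape = .data$admissible)) +
    ggplot2::geom_line(linetype = 3) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "Number of classes G", y = "BIC",
                  shape = "Admissible") +
    ggplot2::theme_minimal()
}

#' Label a fitted trajectory by archetype
#'
#' Classifies a quadratic class curve over weeks `[1, T]` as `FLAT` when
#' its relative range (max minus min over the interval, divided by the mean
#' level) is below `flat_tolerance`, and otherwise by its endpoint slopes:
#' rising at both ends is `UP`, falling at both is `DOWN`, rising then
#' falling is `UP_DOWN`, and falling then rising is `DOWN_UP`.
#'
#' @param beta Length-3 week-scale coefficients of one class.
#' @param T Last week of the observation window (`>= 2`).
#' @param flat_tolerance Relative-range threshold below which a curve is
#'   `FLAT` (default 0.10).
#' @return One of `"UP"`, `"DOWN"`, `"UP_DOWN"`, `"DOWN_UP"`, `"FLAT"`.
#' @export
#' @examples
#' label_archetype(c(6000, 50, 0), 52)          # UP
#' label_archetype(c(5000, 200, -2.5), 52)      # UP_DOWN
label_archetype <- function(beta, T, flat_tolerance = 0.10) {
  stopifnot(T >= 2)
  cand <- c(1, T)
  if (beta[3] != 0) {
    vertex <- -beta[2] / (2 * beta[3])
    if (vertex > 1 && vertex < T) cand <- c(cand, vertex)
  }
  vals <- class_mean(beta, cand)
  level <- mean(class_mean(beta, seq_len(T)))
  rel_range <- if (level > 0) (max(vals) - min(vals)) / level else Inf
  if (rel_range < flat_tolerance) return("FLAT")
  s1 <- beta[2] + 2 * beta[3] * 1
  sT <- beta[2] + 2 * beta[3] * T
  if (s1 >= 0 && sT >= 0) "UP"
  else if (s1 <= 0 && sT <= 0) "DOWN"
  else if (s1 > 0 && sT < 0) "UP_DOWN"
  else "DOWN_UP"
}

#' Archetype labels for every class of a fit
#'
#' @param fit A `steptraj_lcmm`.
#' @inheritParams label_archetype
#' @return A tibble `class`, `archetype` plus the class curve coefficients
#'   and shares.
#' @export
label_classes <- function(fit, flat_tolerance = 0.10) {
  lab <- vapply(seq_len(fit$G), function(g) {
    label_archetype(fit$beta[g, ], fit$Tmax, flat_tolerance)
  }, character(1))
  tidy(fit) %>% mutate(archetype = lab, .after = "class")
}
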