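# Closed-form building blocks of the latent class mixed model.
#
# Per class g the weekly series of participant i is modelled as
#   Y_ij = beta0g + beta1g * t_ij + beta2g * t_ij^2 + u_i + eps_ij,
# with a shared random intercept u_i ~ N(0, sigma_u^2) and residual
# eps_ij ~ N(0, sigma_eps^2). Marginally the series is multivariate normal
# with a compound-symmetry covariance, whose determinant and inverse have
# rank-1 closed forms used throughout (never a generic T x T inversion).

#' Class-specific mean curve
#'
#' Evaluates the quadratic fixed-effect mean `beta0 + beta1 t + beta2 t^2`
#' of a latent class at elapsed week `t`.
#'
#' @param beta Numeric length-3 vector `(beta0, beta1, beta2)` on the
#'   elapsed-week scale.
#' @param t Elapsed week(s); vectorised.
#' @return Steps/day at each `t`.
#' @export
#' @examples
#' class_mean(c(5000, 100, -1), 50)  # 7500
class_mean <- function(beta, t) {
  stopifnot(length(beta) == 3L, all(is.finite(beta)), all(is.finite(t)))
  beta[1] + beta[2] * t + beta[3] * t^2
}

#' Marginal covariance of a weekly series
#'
#' The random intercept plus independent residuals induce compound
#' symmetry: `sigma_u^2` everywhere off the diagonal and
#' `sigma_u^2 + sigma_eps^2` on it.
#'
#' @param sigma_u Random-intercept SD (steps/day), `>= 0`.
#' @param sigma_eps Residual SD (steps/day), `> 0`.
#' @param T Series length (number of weeks).
#' @return A `T x T` positive-definite matrix.
#' @export
marginal_cov <- function(sigma_u, sigma_eps, T) {
  stopifnot(T >= 1, sigma_u >= 0)
  if (sigma_eps <= 0) abort("`sigma_eps` must be positive",
                            class = "steptraj_singular_error")
  matrix(sigma_u^2, T, T) + diag(sigma_eps^2, T)
}

#' Prior class-membership probabilities
#'
#' Softmax of the class-membership intercepts `gamma` (the last entry is
#' fixed at 0 for identifiability).
#'
#' @param gamma Numeric vector of length `G`.
#' @return A probability vector summing to 1.
#' @export
#' @examples
#' prior_probs(c(log(3), 0))  # 0.75 0.25
prior_probs <- function(gamma) {
  stopifnot(all(is.finite(gamma)))
  e <- exp(gamma - max(gamma))
  e / sum(e)
}

# core compound-symmetry log-density pieces for one series length T:
# given residual sums S and sums of squares SSQ (any shape), return the
# log-density parts. kappa = sigma_u^2 / (sigma_eps^2 + T sigma_u^2).
cs_logdens <- function(ssq, S, T, su2, se2) {
  denom <- se2 + T * su2
  quad <- (ssq - su2 * S^2 / denom) / se2
  logdet <- (T - 1) * log(se2) + log(denom)
  -0.5 * (T * log(2 * pi) + logdet + quad)
}

#' Per-class log-likelihood of one participant's series
#'
#' Multivariate-normal log density of a weekly vector with the class mean
#' curve and the compound-symmetry covariance, computed via the rank-1
#' closed form.
#'
#' @param params List with `beta` (a `G x 3` matrix of week-scale
#'   coefficients), `gamma`, `sigma_u`, `sigma_eps`.
#' @param g Class index.
#' @param y Numeric vector of weekly mean steps.
#' @param weeks Elapsed weeks of `y` (defaults to `1:length(y)`).
#' @return The log density (scalar).
#' @export
class_loglik <- function(params, g, y, weeks = seq_along(y)) {
  if (!all(is.finite(y))) abort("series contains non-finite values",
                                class = "steptraj_input_error")
  if (params$sigma_eps <= 0) abort("`sigma_eps` must be positive",
                                   class = "steptraj_singular_error")
  mu <- class_mean(params$beta[g, ], weeks)
  e <- y - mu
  cs_logdens(sum(e^2), sum(e), length(y),
             params$sigma_u^2, params$sigma_eps^2)
}

# split a long weekly tibble into groups of equal series length:
# list(T = , ids = , Y = n x T matrix); weeks must be 1..T per participant
weekly_groups <- function(weekly) {
  stopifnot(all(c("participant_id", "week", "mean_steps") %in% names(weekly)))
  weekly <- arrange(weekly, .data$participant_id, .data$week)
  sp <- split(weekly$mean_steps, weekly$participant_id)
  wk <- split(weekly$week, weekly$participant_id)
  lens <- lengths(sp)
  bad <- !purrr::map2_lgl(wk, lens, ~ identical(as.integer(.x),
                                                seq_len(.y)))
  if (any(bad)) {
    abort(paste0("weekly series must cover weeks 1..T; offending ids: ",
                 paste(head(names(sp)[bad], 5), collapse = ", ")),
          class = "steptraj_input_error")
  }
  out <- lapply(sort(unique(lens)), function(T) {
    sel <- lens == T
    list(T = as.integer(T), ids = names(sp)[sel],
         Y = do.call(rbind, sp[sel]))
  })
  out
}

# per-group sufficient statistics against G class mean curves evaluated on
# an n x T data matrix: residual sums S (n x G) and squares SSQ (n x G)
group_resid_stats <- function(Y, mu) {
  # mu: T x G matrix of class means at weeks 1..T
  rs <- rowSums(Y)
  rq <- rowSums(Y^2)
  C <- Y %*% mu                      # n x G cross terms
  mS <- colSums(mu)
  mQ <- colSums(mu^2)
  list(S = outer(rs, mS, "-"),
       SSQ = sweep(-2 * C, 1, rq, "+") +
         matrix(mQ, nrow(Y), ncol(mu), byrow = TRUE))
}

# n x G matrix of per-class log densities for one group
group_class_loglik <- function(Y, mu, su2, se2) {
  st <- group_resid_stats(Y, mu)
  cs_logdens(st$SSQ, st$S, ncol(Y), su2, se2)
}

# evaluate week-scale class mean curves at weeks 1..T -> T x G matrix
curves_at <- function(beta, T) {
  t <- seq_len(T)
  X <- cbind(1, t, t^2)
  X %*% t(beta)
}

# internal engine: per-participant n x G log-density matrix plus ids,
# for week-scale params on a weekly tibble or precomputed groups
all_class_logliks <- function(params, weekly) {
  groups <- if (is.list(weekly) && !is.data.frame(weekly)) weekly
            else weekly_groups(weekly)
  su2 <- params$sigma_u^2
  se2 <- params$sigma_eps^2
  res <- lapply(groups, function(gr) {
    mu <- curves_at(params$beta, gr$T)
    list(ids = gr$ids, ll = group_class_loglik(gr$Y, mu, su2, se2))
  })
  ids <- unlist(lapply(res, `[[`, "ids"))
  ll <- do.call(rbind, lapply(res, `[[`, "ll"))
  rownames(ll) <- ids
  ll
}

#' Marginal log-likelihood of the latent class mixed model
#'
#' Sum over participants of the log of the prior-weighted mixture of
#' per-class multivariate-normal densities, computed in log space.
#'
#' @inheritParams class_loglik
#' @param weekly Long weekly tibble (`participant_id`, `week`,
#'   `mean_steps`) with each series covering weeks `1..T`.
#' @return The scalar log-likelihood.
#' @export
marginal_loglik <- function(params, weekly) {
  ll <- all_class_logliks(params, weekly)
  logpi <- log(pmax(prior_probs(params$gamma), 1e-300))
  sum(row_logsumexp(sweep(ll, 2, logpi, "+")))
}

#' Posterior class-membership probabilities
#'
#' Bayes-rule responsibilities of each class for each participant, computed
#' in log space; rows sum to 1.
#'
#' @inheritParams marginal_loglik
#' @return An `N x G` matrix with participant ids as row names.
#' @export
posterior_probs <- function(params, weekly) {
  ll <- all_class_logliks(params, weekly)
  logpi <- log(pmax(prior_probs(params$gamma), 1e-300))
  lp <- sweep(ll, 2, logpi, "+")
  w <- exp(lp - row_logsumexp(lp))
  w / rowSums(w)
}
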