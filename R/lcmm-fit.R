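# Maximum-likelihood estimation of the latent class mixed model.
#
# EM: the E-step computes class responsibilities; the M-step updates the
# class curves by weighted GLS against the compound-symmetry covariance,
# the membership intercepts in closed form, and the two variance components
# by the closed-form M-step of the EM that treats the random intercept as
# latent data. Every update increases the marginal log-likelihood. A
# damped Newton (Marquardt-ridge) polish is then applied to the best start.
# Internally time is mapped to [0, 1] for conditioning; reported
# coefficients are on the elapsed-week scale.

#' Bayesian information criterion for an LCMM
#'
#' `-2 loglik + k log(N)` with `k = 3G + (G - 1) + 2` free parameters
#' (three curve coefficients per class, `G - 1` membership intercepts, and
#' the two variance components).
#'
#' @param loglik Maximised marginal log-likelihood.
#' @param G Number of latent classes.
#' @param N Number of participants.
#' @return The BIC (lower is better).
#' @export
lcmm_bic <- function(loglik, G, N) {
  k <- 3 * G + (G - 1) + 2
  -2 * loglik + k * log(N)
}

# scaled design matrix for weeks 1..T with s = (t-1)/b
scaled_design <- function(T, b) {
  s <- (seq_len(T) - 1) / b
  cbind(1, s, s^2)
}

# scaled-basis coefficients -> week-scale (beta0, beta1, beta2)
to_week_scale <- function(B, b) {
  cbind(B[, 1] - B[, 2] / b + B[, 3] / b^2,
        B[, 2] / b - 2 * B[, 3] / b^2,
        B[, 3] / b^2)
}

# per-group cached pieces used throughout one fit
fit_groups <- function(weekly) {
  groups <- weekly_groups(weekly)
  Tmax <- max(vapply(groups, `[[`, integer(1), "T"))
  b <- max(Tmax - 1L, 1L)
  for (k in seq_along(groups)) {
    gr <- groups[[k]]
    X <- scaled_design(gr$T, b)
    groups[[k]]$X <- X
    groups[[k]]$XtX <- crossprod(X)
    groups[[k]]$Xt1 <- colSums(X)
    groups[[k]]$rs <- rowSums(gr$Y)
    groups[[k]]$rq <- rowSums(gr$Y^2)
    groups[[k]]$n <- nrow(gr$Y)
  }
  list(groups = groups, Tmax = Tmax, b = b,
       N = sum(vapply(groups, `[[`, integer(1), "n")),
       sumT = sum(vapply(groups, function(g) g$n * g$T, numeric(1))))
}

# log-density matrices (list over groups of n x G) for scaled-basis params
gll_scaled <- function(gd, B, su2, se2) {
  lapply(gd$groups, function(gr) {
    mu <- gr$X %*% t(B)
    S <- outer(gr$rs, colSums(mu), "-")
    SSQ <- sweep(-2 * (gr$Y %*% mu), 1, gr$rq, "+") +
      matrix(colSums(mu^2), gr$n, ncol(mu), byrow = TRUE)
    cs_logdens(SSQ, S, gr$T, su2, se2)
  })
}

ll_scaled <- function(gd, B, gamma, su2, se2) {
  logpi <- log(pmax(prior_probs(gamma), 1e-300))
  sum(vapply(gll_scaled(gd, B, su2, se2), function(ll) {
    sum(row_logsumexp(sweep(ll, 2, logpi, "+")))
  }, numeric(1)))
}

# one EM run from an initial parameter state
run_em <- function(gd, init, max_iter, tol) {
  B <- init$B; gamma <- init$gamma
  su2 <- init$su2; se2 <- init$se2
  G <- nrow(B)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  W <- NULL

  for (iter in seq_len(max_iter)) {
    ## E-step
    logpi <- log(pmax(prior_probs(gamma), 1e-300))
    lls <- gll_scaled(gd, B, su2, se2)
    ll <- 0
    W <- vector("list", length(lls))
    for (k in seq_along(lls)) {
      lp <- sweep(lls[[k]], 2, logpi, "+")
      lse <- row_logsumexp(lp)
      ll <- ll + sum(lse)
      w <- exp(lp - lse)
      W[[k]] <- w / rowSums(w)
    }
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_prev <- ll

    ## M-step: priors
    pi <- Reduce(`+`, lapply(W, colSums)) / gd$N
    pi <- pmax(pi, 1e-10)
    pi <- pi / sum(pi)
    gamma <- log(pi) - log(pi[G])

    ## M-step: class curves by weighted GLS under compound symmetry
    for (g in seq_len(G)) {
      A <- matrix(0, 3, 3)
      bvec <- numeric(3)
      for (k in seq_along(gd$groups)) {
        gr <- gd$groups[[k]]
        wg <- W[[k]][, g]
        kap <- su2 / (se2 + gr$T * su2)
        A <- A + (sum(wg) * (gr$XtX - kap * tcrossprod(gr$Xt1))) / se2
        zg <- crossprod(gr$Y, wg)                 # T x 1
        bvec <- bvec + (crossprod(gr$X, zg)[, 1] -
                          kap * gr$Xt1 * sum(wg * gr$rs)) / se2
      }
      B[g, ] <- solve(A + diag(1e-10, 3), bvec)
    }

    ## M-step: variance components (random intercept as latent data)
    num_u <- 0; num_e <- 0
    for (k in seq_along(gd$groups)) {
      gr <- gd$groups[[k]]
      mu <- gr$X %*% t(B)
      S <- outer(gr$rs, colSums(mu), "-")
      SSQ <- sweep(-2 * (gr$Y %*% mu), 1, gr$rq, "+") +
        matrix(colSums(mu^2), gr$n, G, byrow = TRUE)
      v <- su2 * se2 / (se2 + gr$T * su2)
      m <- v * S / se2
      num_u <- num_u + sum(W[[k]] * (m^2 + v))
      num_e <- num_e + sum(W[[k]] * (SSQ - 2 * m * S + gr$T * (m^2 + v)))
    }
    su2 <- max(num_u / gd$N, 0)
    se2 <- max(num_e / gd$sumT, 1e-8)
  }

  list(B = B, gamma = gamma, su2 = su2, se2 = se2,
       loglik = trace[length(trace)], trace = trace,
       converged = converged, n_iter = length(trace))
}

# damped Newton (Marquardt ridge) polish on the full parameter vector
newton_polish <- function(gd, fitpars, max_steps = 50, se_floor = 1e-4) {
  G <- nrow(fitpars$B)
  pack <- function(p) c(as.vector(p$B), p$gamma[seq_len(G - 1)],
                        0.5 * log(max(p$su2, se_floor^2)),
                        0.5 * log(p$se2))
  unpack <- function(th) {
    B <- matrix(th[seq_len(3 * G)], G, 3)
    gamma <- c(th[3 * G + seq_len(G - 1)], 0)
    if (G == 1) gamma <- 0
    list(B = B, gamma = gamma,
         su2 = exp(2 * th[3 * G + G]), se2 = exp(2 * th[3 * G + G + 1]))
  }
  f <- function(th) {
    p <- unpack(th)
    ll_scaled(gd, p$B, p$gamma, p$su2, p$se2)
  }
  np <- 3 * G + (G - 1) + 2
  grad <- function(th) {
    g <- numeric(np)
    for (j in seq_len(np)) {
      h <- 1e-5 * (1 + abs(th[j]))
      tp <- th; tm <- th
      tp[j] <- th[j] + h; tm[j] <- th[j] - h
      g[j] <- (f(tp) - f(tm)) / (2 * h)
    }
    g
  }

  th <- pack(fitpars)
  ll <- f(th)
  trace <- numeric(0)
  lambda <- 1e-3
  for (step in seq_len(max_steps)) {
    g <- grad(th)
    # scale-aware stationarity check: predicted gain of a unit-scaled move
    if (max(abs(g) * (1 + abs(th))) < 1e-4) break
    H <- matrix(0, np, np)
    for (j in seq_len(np)) {
      h <- 1e-4 * (1 + abs(th[j]))
      tp <- th; tm <- th
      tp[j] <- th[j] + h; tm[j] <- th[j] - h
      H[, j] <- (grad_at(gd, tp, f, np) - grad_at(gd, tm, f, np)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    improved <- FALSE
    for (inner in 1:12) {
      D <- diag(pmax(abs(diag(H)), 1e-8), np)
      d <- tryCatch(solve(-H + lambda * D, g), error = function(e) NULL)
      if (!is.null(d)) {
        th_new <- th + d
        ll_new <- tryCatch(f(th_new), error = function(e) -Inf)
        if (is.finite(ll_new) && ll_new > ll) {
          th <- th_new
          improved <- TRUE
          lambda <- max(lambda / 10, 1e-10)
          trace <- c(trace, ll_new)
          gain <- ll_new - ll
          ll <- ll_new
          if (gain < 1e-9 * (1 + abs(ll))) improved <- "done"
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!isTRUE(improved)) break
  }
  out <- unpack(th)
  out$loglik <- ll
  out$trace <- trace
  out
}

grad_at <- function(gd, th, f, np) {
  g <- numeric(np)
  for (j in seq_len(np)) {
    h <- 1e-5 * (1 + abs(th[j]))
    tp <- th; tm <- th
    tp[j] <- th[j] + h; tm[j] <- th[j] - h
    g[j] <- (f(tp) - f(tm)) / (2 * h)
  }
  g
}

# starting values: k-means on per-participant level and linear trend
# (robust low-dimensional summaries of each series), then pooled quadratic
# OLS per cluster; further starts jitter the resulting class curves
make_init <- function(gd, G, start, seed) {
  set.seed(sub_seed(seed, 9000 + start))
  feats <- do.call(rbind, lapply(gd$groups, function(gr) {
    s <- gr$X[, 2]
    sc <- s - mean(s)
    slope <- if (sum(sc^2) > 0) as.vector(gr$Y %*% sc) / sum(sc^2) else
      rep(0, gr$n)
    cbind(rowMeans(gr$Y), slope)
  }))
  if (G == 1) {
    cl <- rep(1L, nrow(feats))
  } else {
    sc <- scale(feats)
    sc[!is.finite(sc)] <- 0
    km <- tryCatch(kmeans(sc, centers = G, nstart = 10, iter.max = 100),
                   error = function(e) NULL)
    cl <- if (is.null(km)) {
      as.integer(cut(rank(feats[, 1], ties.method = "first"), G,
                     labels = FALSE))
    } else km$cluster
  }
  # pooled OLS quadratic fit per cluster (shrinks the noisy per-person
  # curvature that a per-participant quadratic would carry)
  B <- matrix(0, G, 3)
  for (g in seq_len(G)) {
    A <- diag(1e-8, 3)
    bvec <- numeric(3)
    i0 <- 0
    for (gr in gd$groups) {
      idx <- i0 + seq_len(gr$n)
      sel <- cl[idx] == g
      if (any(sel)) {
        A <- A + sum(sel) * gr$XtX
        bvec <- bvec + crossprod(gr$X, colSums(gr$Y[sel, , drop = FALSE]))
      }
      i0 <- i0 + gr$n
    }
    B[g, ] <- if (sum(abs(bvec)) > 0) solve(A, bvec) else
      c(mean(feats[, 1]), 0, 0)
  }
  pi <- pmax(tabulate(cl, G) / nrow(feats), 1e-3)
  pi <- pi / sum(pi)

  # crude variance split: within-person residual spread vs level spread
  resid_mean <- numeric(0); resid_var <- numeric(0)
  i0 <- 0
  for (gr in gd$groups) {
    idx <- i0 + seq_len(gr$n)
    mu <- gr$X %*% t(B)
    R <- gr$Y - t(mu[, cl[idx], drop = FALSE])
    resid_mean <- c(resid_mean, rowMeans(R))
    resid_var <- c(resid_var, apply(R, 1, var))
    i0 <- i0 + gr$n
  }
  su2 <- max(var(resid_mean), 1)
  se2 <- max(mean(resid_var, na.rm = TRUE), 1)

  if (start > 1) {
    jit <- apply(B, 2, function(x) max(stats::sd(x), abs(mean(x)) * 0.05, 1))
    B <- B + matrix(rnorm(length(B)), nrow(B)) * rep(jit, each = nrow(B)) * 0.5
  }
  list(B = B, gamma = log(pi) - log(pi[G]), su2 = su2, se2 = se2)
}

#' Fit a latent class mixed model to weekly step series
#'
#' Maximum-likelihood estimation of a `G`-class mixture of quadratic mean
#' curves with a shared random intercept and residual variance. The
#' marginal likelihood is maximised by EM (responsibilities; weighted-GLS
#' curve updates; closed-form membership and variance updates) from
#' `n_starts` initialisations (k-means on per-participant quadratic
#' coefficients, then jittered), followed by a damped-Newton polish of the
#' best start. Classes are reported in order of descending fitted mean
#' level so labels are stable across runs; assignment ties go to the
#' lowest (largest-mean) class index.
#'
#' @param weekly Long tibble `participant_id`, `week`, `mean_steps`; each
#'   participant's series must cover weeks `1..T` (series lengths may
#'   differ between participants).
#' @param G Number of latent classes (`N >= G`).
#' @param n_starts Number of EM initialisations.
#' @param seed Integer seed controlling initialisation and jitter.
#' @param max_iter Maximum EM iterations per start.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param newton_steps Maximum damped-Newton polish steps.
#'
#' @return A `steptraj_lcmm` object: week-scale `beta` (`G x 3`), `gamma`,
#'   `pi`, `sigma_u`, `sigma_eps`, `loglik`, `bic`, `posterior` (`N x G`),
#'   `assignment` tibble, `mean_posterior`, `class_counts`, convergence
#'   metadata and the EM log-likelihood `trace`.
#' @export
fit_lcmm <- function(weekly, G, n_starts = 3, seed = 1L, max_iter = 500,
                     tol = 1e-8, newton_steps = 50) {
  withr::local_preserve_seed()
  gd <- fit_groups(weekly)
  if (gd$N < G) abort("need at least G participants",
                      class = "steptraj_input_error")

  best <- NULL
  traces <- list()
  for (s in seq_len(n_starts)) {
    init <- make_init(gd, G, s, seed)
    em <- tryCatch(run_em(gd, init, max_iter, tol), error = function(e) NULL)
    if (is.null(em)) next
    traces[[s]] <- em$trace
    if (is.null(best) || em$loglik > best$loglik) best <- em
  }
  if (is.null(best)) {
    abort("no EM start converged to a finite likelihood",
          class = "steptraj_nonconvergence_error")
  }

  pol <- newton_polish(gd, best, max_steps = newton_steps)
  if (pol$loglik >= best$loglik) {
    best$B <- pol$B; best$gamma <- pol$gamma
    best$su2 <- pol$su2; best$se2 <- pol$se2
    best$loglik <- pol$loglik
  }

  ## canonical ordering by descending mean fitted level over the window
  beta <- to_week_scale(best$B, gd$b)
  lev <- colMeans(curves_at(beta, gd$Tmax))
  ord <- order(lev, decreasing = TRUE)
  beta <- beta[ord, , drop = FALSE]
  B <- best$B[ord, , drop = FALSE]
  pi <- prior_probs(best$gamma)[ord]
  gamma <- log(pi) - log(pi[G])
  sigma_u <- sqrt(best$su2)
  sigma_eps <- sqrt(best$se2)

  params <- list(beta = beta, gamma = gamma, pi = pi,
                 sigma_u = sigma_u, sigma_eps = sigma_eps)
  post <- posterior_probs(params, weekly)
  assignment_idx <- max.col(post, ties.method = "first")
  class_counts <- tabulate(assignment_idx, G)
  mean_posterior <- vapply(seq_len(G), function(g) {
    sel <- assignment_idx == g
    if (any(sel)) mean(post[sel, g]) else NA_real_
  }, numeric(1))

  structure(
    list(G = G,
         beta = beta,
         gamma = gamma,
         pi = pi,
         sigma_u = sigma_u,
         sigma_eps = sigma_eps,
         loglik = best$loglik,
         bic = lcmm_bic(best$loglik, G, gd$N),
         posterior = post,
         assignment = tibble(participant_id = rownames(post),
                             class = assignment_idx,
                             posterior = post[cbind(seq_len(nrow(post)),
                                                    assignment_idx)]),
         mean_posterior = mean_posterior,
         class_counts = class_counts,
         converged = best$converged,
         n_iterations = best$n_iter,
         n_starts_used = length(traces),
         trace = best$trace,
         N = gd$N,
         Tmax = gd$Tmax),
    class = "steptraj_lcmm"
  )
}

#' @export
print.steptraj_lcmm <- function(x, digits = 4, ...) {
  cat(sprintf("Latent class mixed model: G = %d, N = %d, T <= %d\n",
              x$G, x$N, x$Tmax))
  cat(sprintf("  loglik %.3f, BIC %.3f, sigma_u %.1f, sigma_eps %.1f%s\n",
              x$loglik, x$bic, x$sigma_u, x$sigma_eps,
              if (x$converged) "" else "  [not converged]"))
  tab <- tidy(x)
  print(as.data.frame(tab), digits = digits, row.names = FALSE)
  invisible(x)
}

#' @rdname fit_lcmm
#' @param x A `steptraj_lcmm` object.
#' @param ... Unused.
#' @export
tidy.steptraj_lcmm <- function(x, ...) {
  tibble(class = seq_len(x$G),
         beta0 = x$beta[, 1], beta1 = x$beta[, 2], beta2 = x$beta[, 3],
         pi = x$pi,
         n = x$class_counts,
         share = x$class_counts / x$N,
         mean_posterior = x$mean_posterior)
}

#' @rdname fit_lcmm
#' @export
glance.steptraj_lcmm <- function(x, ...) {
  tibble(G = x$G, N = x$N, loglik = x$loglik, bic = x$bic,
         sigma_u = x$sigma_u, sigma_eps = x$sigma_eps,
         converged = x$converged, n_iterations = x$n_iterations)
}

#' @rdname fit_lcmm
#' @param object A `steptraj_lcmm` object.
#' @export
autoplot.steptraj_lcmm <- function(object, ...) {
  curves <- tidyr::crossing(class = seq_len(object$G),
                            week = seq_len(object$Tmax)) %>%
    mutate(mean_steps = purrr::map2_dbl(
      .data$class, .data$week,
      ~ class_mean(object$beta[.x, ], .y)))
  ggplot2::ggplot(curves, ggplot2::aes(.data$week, .data$mean_steps,
                                       colour = factor(.data$class))) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "Elapsed week", y = "Mean steps/day",
                  colour = "Class") +
    ggplot2::theme_minimal()
}

#' Mean fitted steps per class over two periods
#'
#' Averages each fitted class curve over weeks `1..split` and
#' `(split+1)..T`, the two-period summary conventionally used to describe
#' step trajectories.
#'
#' @param fit A `steptraj_lcmm`.
#' @param split Last week of the first period.
#' @return A tibble with one row per class: `period1`, `period2`.
#' @export
period_class_means <- function(fit, split = 28L) {
  Tmax <- fit$Tmax
  w1 <- seq_len(min(split, Tmax))
  w2 <- if (Tmax > split) seq.int(split + 1L, Tmax) else integer(0)
  tibble(
    class = seq_len(fit$G),
    period1 = vapply(seq_len(fit$G),
                     function(g) mean(class_mean(fit$beta[g, ], w1)),
                     numeric(1)),
    period2 = vapply(seq_len(fit$G), function(g) {
      if (length(w2)) mean(class_mean(fit$beta[g, ], w2)) else NA_real_
    }, numeric(1))
  )
}

#' Serialise a fitted LCMM to structured text
#'
#' Writes the parameters and convergence metadata as JSON and the posterior
#' matrix as a delimited long table (`participant_id`, `class`,
#' `probability`).
#'
#' @param fit A `steptraj_lcmm`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two paths written.
#' @export
write_lcmm_fit <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(G = fit$G, N = fit$N, beta = fit$beta, gamma = fit$gamma,
               pi = fit$pi, sigma_u = fit$sigma_u,
               sigma_eps = fit$sigma_eps, loglik = fit$loglik,
               bic = fit$bic, converged = fit$converged,
               n_iterations = fit$n_iterations,
               n_starts_used = fit$n_starts_used)
  p1 <- file.path(dir, "lcmm_fit.json")
  jsonlite::write_json(meta, p1, auto_unbox = TRUE, digits = NA)
  post <- as_tibble(fit$posterior, .name_repair = ~ paste0("c", seq_len(fit$G)))
  post$participant_id <- rownames(fit$posterior)
  long <- tidyr::pivot_longer(post, -"participant_id",
                              names_to = "class", values_to = "probability") %>%
    mutate(class = as.integer(sub("^c", "", .data$class)))
  p2 <- file.path(dir, "posterior.csv")
  readr::write_csv(long, p2)
  invisible(c(p1, p2))
}
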