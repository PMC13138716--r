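# Independent oracles and small simulators used across the suite.

# dense multivariate-normal log density via a generic Cholesky factorisation
# (the package path uses the rank-1 compound-symmetry closed form instead)
dense_mvn_logdens <- function(y, mu, Sigma) {
  ch <- chol(Sigma)
  z <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# brute-force term-by-term mixture log-likelihood and posteriors on a
# weekly tibble, using dense densities and direct (non-log-space) sums
brute_force_mixture <- function(params, weekly) {
  ids <- unique(weekly$participant_id)
  G <- nrow(params$beta)
  pi <- exp(params$gamma) / sum(exp(params$gamma))
  dens <- matrix(NA_real_, length(ids), G, dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    d <- weekly[weekly$participant_id == ids[i], ]
    d <- d[order(d$week), ]
    T <- nrow(d)
    Sigma <- matrix(params$sigma_u^2, T, T) + diag(params$sigma_eps^2, T)
    for (g in seq_len(G)) {
      mu <- params$beta[g, 1] + params$beta[g, 2] * d$week +
        params$beta[g, 3] * d$week^2
      dens[i, g] <- exp(dense_mvn_logdens(d$mean_steps, mu, Sigma))
    }
  }
  mix <- dens %*% pi
  list(loglik = sum(log(mix)),
       posterior = sweep(dens, 2, pi, "*") / as.vector(mix))
}

# random small LCMM parameter set + weekly data for oracle equivalence
random_lcmm_instance <- function(N = 4, Tmax = 5, G = 2) {
  beta <- cbind(runif(G, 3000, 9000), runif(G, -100, 100),
                runif(G, -2, 2))
  params <- list(beta = beta,
                 gamma = c(rnorm(G - 1, 0, 1), 0),
                 sigma_u = runif(1, 100, 1500),
                 sigma_eps = runif(1, 200, 1500))
  weekly <- dplyr::bind_rows(lapply(seq_len(N), function(i) {
    T <- sample(2:Tmax, 1)
    g <- sample(G, 1)
    mu <- beta[g, 1] + beta[g, 2] * seq_len(T) + beta[g, 3] * seq_len(T)^2
    tibble::tibble(participant_id = sprintf("i%02d", i),
                   week = seq_len(T),
                   mean_steps = mu + rnorm(1, 0, params$sigma_u) +
                     rnorm(T, 0, params$sigma_eps))
  }))
  list(params = params, weekly = weekly)
}

# direct weekly-series simulator (bypasses the daily layer) for fit tests
simulate_weekly <- function(n_per_class, beta, sigma_u, sigma_eps, T,
                            seed = 1) {
  withr::with_seed(seed, {
    G <- nrow(beta)
    rows <- list()
    k <- 0
    for (g in seq_len(G)) {
      for (i in seq_len(n_per_class[g])) {
        k <- k + 1
        mu <- beta[g, 1] + beta[g, 2] * seq_len(T) + beta[g, 3] * seq_len(T)^2
        rows[[k]] <- tibble::tibble(
          participant_id = sprintf("s%04d", k),
          week = seq_len(T),
          mean_steps = mu + rnorm(1, 0, sigma_u) + rnorm(T, 0, sigma_eps),
          true_class = g)
      }
    }
    dplyr::bind_rows(rows)
  })
}

# best-permutation agreement between fitted assignment and true classes
match_accuracy <- function(fitted, true, G) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(G))) {
    best <- max(best, mean(p[fitted] == true))
  }
  best
}

# labeled per-participant fixture with the reference cohort's per-class
# outcome counts (355/193/2045/185 participants; 75/47/457/76 events)
table2_fixture <- function() {
  mk <- function(arch, n, n_loss) {
    tibble::tibble(archetype = arch,
                   outcome = rep(c(1L, 0L), c(n_loss, n - n_loss)))
  }
  dplyr::bind_rows(mk("DOWN", 355, 75), mk("UP_DOWN", 193, 47),
                   mk("FLAT", 2045, 457), mk("UP", 185, 76))
}

# vectorised outcome-row simulator for logistic-regression tests
simulate_outcome_rows <- function(n, up_logodds, seed,
                                  shares = c(FLAT = 0.736, UP = 0.067,
                                             DOWN = 0.128, UP_DOWN = 0.069),
                                  intercept = qlogis(0.223)) {
  withr::with_seed(seed, {
    cls <- sample(names(shares), n, replace = TRUE, prob = shares)
    age <- round(pmin(pmax(rnorm(n, 65, 8.1), 40), 74))
    sex <- rbinom(n, 1, 0.576)
    smoking <- rbinom(n, 1, 0.075)
    medication <- rbinom(n, 1, 0.638)
    mean_steps_k <- pmax(rnorm(n, 5.8, 3), 0.5)
    eff <- c(FLAT = 0, UP = up_logodds, DOWN = -0.069, UP_DOWN = 0.118)
    lin <- intercept + eff[cls] - 0.01 * (age - 65) + 0.1 * sex +
      0.1 * smoking - 0.1 * medication + log(1.01) * (mean_steps_k - 5.8)
    tibble::tibble(archetype = cls, outcome = rbinom(n, 1, plogis(lin)),
                   age = age, sex = sex, smoking = smoking,
                   medication = medication, mean_steps_k = mean_steps_k)
  })
}
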