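# Independent oracles, written as explicit scalar recomputations so they
# share no code path with the package internals.

# per-trial scalar log-likelihood of the prospect-utility Q-learning model
oracle_loglik <- function(record, params) {
  q <- c(right = 0, left = 0)
  ll <- 0
  for (t in seq_along(record$trial)) {
    x <- params$beta * q
    m <- max(x)
    logp <- (x - m) - log(exp(x[["right"]] - m) + exp(x[["left"]] - m))
    ch <- record$choice[t]
    ll <- ll + logp[[ch]]
    r <- record$reward[t]
    u <- if (r > 0) r^params$mu
         else if (r < 0) -params$lam * (-r)^params$nu else 0
    d <- u - q[[ch]]
    a <- if (d >= 0) params$alpha_pos else params$alpha_neg
    q[[ch]] <- q[[ch]] + a * d + params$phi
  }
  ll
}

# Newton-scored probit regression with expected (Fisher) information
oracle_probit <- function(y, X, iter = 100) {
  b <- rep(0, ncol(X))
  info <- NULL
  for (i in seq_len(iter)) {
    eta <- drop(X %*% b)
    p <- pmin(pmax(stats::pnorm(eta), 1e-12), 1 - 1e-12)
    d <- stats::dnorm(eta)
    score <- drop(t(X) %*% (d * (y - p) / (p * (1 - p))))
    info <- t(X) %*% (X * (d^2 / (p * (1 - p))))
    step <- solve(info, score)
    b <- b + step
    if (max(abs(step)) < 1e-12) break
  }
  ll <- sum(y * log(stats::pnorm(drop(X %*% b))) +
              (1 - y) * log(1 - stats::pnorm(drop(X %*% b))))
  list(coef = b, se = sqrt(diag(solve(info))), log_lik = ll)
}

# Pearson chi-square on a 2x2 count table by the hand formula
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# a record with random choices and +/-10 rewards (the likelihood consumes
# any sequence, schedule-consistent or not)
random_record <- function(n, seed) {
  with_seed(seed, {
    behavioral_record(
      "r", sample(c("right", "left"), n, replace = TRUE),
      sample(c(10, -10), n, replace = TRUE)
    )
  })
}

# parameters drawn from the estimation priors
random_params <- function(seed, phi_bound = 50) {
  with_seed(seed, {
    g <- stats::rgamma(4, shape = 2, scale = 3)
    a <- stats::rbeta(2, 2, 2)
    model_parameters(beta = g[1], mu = g[2], nu = g[3],
                     alpha_pos = a[1], alpha_neg = a[2], lam = g[4],
                     phi = max(-phi_bound, min(phi_bound, stats::rnorm(1))))
  })
}

# small cohort config with flat outcome links, for structural tests
test_config <- function(n = 40, n_inc = 2, n_prior = 3, seed = 1,
                        coef8 = NULL, coef9 = NULL,
                        order_probability = 0.5) {
  zero <- c(intercept = 0, beta = 0, mu = 0, nu = 0, alpha_pos = 0,
            alpha_neg = 0, lam = 0, phi = 0, tab_performance = 0,
            other_success = 0)
  cohort_config(
    n_enrolled = n, n_incomplete = n_inc, n_prior_experience = n_prior,
    trait_distributions = default_study_config()$trait_distributions,
    probit_coefficients_8coin = if (is.null(coef8)) zero else coef8,
    probit_coefficients_9dot = if (is.null(coef9)) zero else coef9,
    order_probability = order_probability, seed = seed
  )
}
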