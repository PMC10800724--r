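make_fitted_cohort <- function(n = 400, seed = 51, coef8 = NULL,
                               coef9 = NULL, order_probability = 0.5) {
  cohort <- apply_exclusions(generate_cohort(
    test_config(n, 0, 0, seed = seed, coef8 = coef8, coef9 = coef9,
                order_probability = order_probability)))
  list(cohort = cohort, fits = true_trait_table(cohort))
}

test_that("intercept-only probit matches the closed-form Bernoulli likelihood", {
  y <- c(rep(1, 13), rep(0, 27))
  fit <- probit_fit(y)
  k <- 13; n <- 40
  ll <- k * log(k / n) + (n - k) * log(1 - k / n)
  expect_equal(fit$log_lik, ll, tolerance = 1e-8)
  expect_equal(fit$aic, 2 - 2 * ll, tolerance = 1e-8)
  expect_equal(unname(stats::pnorm(fit$coefficients["(Intercept)"])), k / n,
               tolerance = 1e-6)
})

test_that("probit flags degenerate outcomes and separation, rejects collinearity", {
  expect_false(probit_fit(rep(1, 30))$converged)
  x <- c(rep(0, 20), rep(1, 20))
  sep <- probit_fit(x, data.frame(x = x)) # perfectly separated
  expect_false(sep$converged)
  expect_error(probit_fit(x, data.frame(a = 1:40, b = 2 * (1:40))),
               "collinear.*b")
  expect_error(probit_fit(c(0, 1, 2), data.frame(x = 1:3)), "binary")
  expect_error(probit_fit(c(0, 1), data.frame(a = 1:2, b = c(2, 1))),
               "more observations")
})

test_that("probit coefficients and SEs match an independent Newton-scored fit", {
  withr::with_seed(61, {
    for (i in 1:10) {
      n <- 200
      X <- cbind(1, matrix(stats::rnorm(3 * n), n, 3))
      b_true <- stats::runif(4, -0.8, 0.8)
      y <- as.integer(stats::runif(n) < stats::pnorm(drop(X %*% b_true)))
      if (length(unique(y)) < 2) next
      df <- data.frame(x1 = X[, 2], x2 = X[, 3], x3 = X[, 4])
      fit <- probit_fit(y, df)
      ora <- oracle_probit(y, X)
      expect_equal(unname(fit$coefficients), unname(ora$coef),
                   tolerance = 1e-6)
      expect_equal(unname(fit$standard_errors), unname(ora$se),
                   tolerance = 1e-4)
      expect_equal(fit$log_lik, ora$log_lik, tolerance = 1e-8)
      expect_equal(fit$aic, 2 * 4 - 2 * fit$log_lik, tolerance = 1e-10)
    }
  })
})

test_that("full-sample regressions use the specified regressor sets", {
  fc <- make_fitted_cohort(n = 400, seed = 71)
  res <- run_table3_analysis(fc$cohort, fc$fits)
  expect_named(res, c("coin8_base", "coin8_transfer", "dot9_base",
                      "dot9_transfer"))
  base_terms <- names(res$coin8_base$coefficients)
  tr_terms <- names(res$coin8_transfer$coefficients)
  expect_setequal(base_terms,
                  c("(Intercept)", param_names(), "tab_performance"))
  expect_setequal(setdiff(tr_terms, base_terms), "success_9dot")
  expect_setequal(setdiff(names(res$dot9_transfer$coefficients),
                          names(res$dot9_base$coefficients)),
                  "success_8coin")
  expect_identical(res$coin8_base$n_obs, 400L)
  # AIC identity for every fit
  for (r in res) {
    expect_equal(r$aic, 2 * length(r$coefficients) - 2 * r$log_lik,
                 tolerance = 1e-10)
  }
  # adding the transfer regressor never lowers the maximized log-likelihood
  expect_gte(res$coin8_transfer$log_lik, res$coin8_base$log_lik - 1e-8)
  expect_gte(res$dot9_transfer$log_lik, res$dot9_base$log_lik - 1e-8)
})

test_that("second-task regressions restrict to the right order subsamples", {
  fc <- make_fitted_cohort(n = 500, seed = 81)
  res <- run_table4_analysis(fc$cohort, fc$fits)
  n8 <- sum(fc$cohort$subjects$task_order == "9dot_first")
  expect_identical(res$coin8_base$n_obs, n8)
  expect_identical(res$dot9_base$n_obs, 500L - n8)
  expect_lt(abs(n8 - 250), 4 * sqrt(500 * 0.25))
  expect_setequal(names(res$coin8_transfer$coefficients),
                  names(run_table3_analysis(fc$cohort,
                                            fc$fits)$coin8_transfer$coefficients))
  all8 <- make_fitted_cohort(n = 120, seed = 82, order_probability = 1)
  expect_error(run_table4_analysis(all8$cohort, all8$fits), "empty second")
})

test_that("regression joins report orphans and drop unconverged fits listwise", {
  fc <- make_fitted_cohort(n = 120, seed = 91)
  short <- fc$fits[-(1:3), ]
  expect_error(run_table3_analysis(fc$cohort, short), "missing from")
  flagged <- fc$fits
  flagged$converged[1:5] <- FALSE
  expect_message(res <- run_table3_analysis(fc$cohort, flagged),
                 "5 subjects")
  expect_identical(res$coin8_base$n_obs, 115L)
})

test_that("order comparison reproduces the hand chi-square formula", {
  # equal proportions give exactly zero
  tab0 <- rbind(c(30, 70), c(30, 70))
  expect_equal(oracle_chisq(tab0), 0)
  tab <- rbind(c(30, 70), c(50, 50))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(unname(ct$statistic), oracle_chisq(tab), tolerance = 1e-12)
  # the design-scale split: proportions 0.25 vs 0.36 at n = 162/163
  n1 <- 162; n2 <- 163
  k1 <- round(0.25 * n1); k2 <- round(0.36 * n2)
  tab2 <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  chi <- oracle_chisq(tab2)
  expect_equal(unname(suppressWarnings(
    stats::chisq.test(tab2, correct = FALSE))$statistic), chi,
    tolerance = 1e-12)
  expect_gt(chi, 0) # value recorded, not asserted against any report

  cohort <- apply_exclusions(generate_cohort(test_config(300, 0, 0, seed = 7)))
  cmp <- success_rate_comparison(cohort, "8coin")
  s <- cohort$subjects
  first <- s$task_order == "8coin_first"
  mytab <- rbind(c(sum(s$success_8coin[first]), sum(1 - s$success_8coin[first])),
                 c(sum(s$success_8coin[!first]), sum(1 - s$success_8coin[!first])))
  expect_equal(cmp$chi_square, oracle_chisq(mytab), tolerance = 1e-10)
  expect_equal(cmp$rate_first, mean(s$success_8coin[first]))
  expect_false(cmp$degenerate)
})

test_that("descriptive statistics expose means, n-1 SDs and null correlations", {
  fc <- make_fitted_cohort(n = 6000, seed = 101)
  d <- descriptive_stats(fc$cohort, fc$fits)
  expect_s3_class(d, "descriptive_table")
  expect_true(all(diag(d$correlations) == 1))
  sub <- fc$cohort$subjects
  expect_equal(d$summary$mean[d$summary$variable == "beta"], mean(sub$beta))
  expect_equal(d$summary$sd[d$summary$variable == "lam"], sd(sub$lam))
  # independently generated traits are uncorrelated at n = 6000
  lower <- d$correlations[lower.tri(d$correlations)]
  traits_only <- d$correlations[param_names(), param_names()]
  off <- traits_only[lower.tri(traits_only)]
  expect_true(all(abs(off) < 0.04))
  expect_true(all(lower >= -1 & lower <= 1, na.rm = TRUE))
  # a constant column yields flagged (NA) correlations, not an error
  const_fits <- fc$fits
  const_fits$phi <- 0
  d2 <- descriptive_stats(fc$cohort, const_fits)
  expect_true(all(is.na(d2$correlations["phi", c("beta", "mu")])))
  expect_error(descriptive_stats(
    apply_exclusions(generate_cohort(test_config(4, 1, 1, seed = 5))),
    data.frame(subject_id = character(), converged = logical())),
    "missing from|at least 3")
})

test_that("probit recovery: fitting a cohort generated with known coefficients", {
  coef8 <- c(intercept = -0.4, beta = 0.1, mu = -0.3, nu = 0.2,
             alpha_pos = 0.3, alpha_neg = -0.6, lam = -0.2, phi = 0.01,
             tab_performance = 0.005, other_success = 0.59)
  fc <- make_fitted_cohort(n = 20000, seed = 111, coef8 = coef8,
                           order_probability = 0) # 8-coin always second
  res <- run_table3_analysis(fc$cohort, fc$fits)$coin8_transfer
  truth <- c(`(Intercept)` = unname(coef8["intercept"]),
             success_9dot = unname(coef8["other_success"]),
             coef8[c(param_names(), "tab_performance")])
  est <- res$coefficients[names(truth)]
  se <- res$standard_errors[names(truth)]
  expect_true(all(abs(est - truth) < 3 * se))
})

test_that("rendered regression tables carry estimates, SEs, stars, AIC and N", {
  fc <- make_fitted_cohort(n = 200, seed = 121)
  res <- run_table3_analysis(fc$cohort, fc$fits)
  lines <- render_regression_table(res)
  expect_true(any(grepl("AIC", lines)))
  expect_true(any(grepl("\\(0\\.", lines)))
  expect_true(any(grepl("lam", lines)))
  expect_identical(significance_marker(c(0.005, 0.03, 0.07, 0.5, NA)),
                   c("***", "**", "*", "", ""))
})
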