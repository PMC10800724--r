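test_that("prospect utility curves gains and scales losses by loss aversion", {
  expect_equal(prospect_utility(10, model_parameters(1, mu = 1)), 10)
  expect_equal(prospect_utility(-10, model_parameters(1, nu = 1, lam = 1)), -10)
  expect_equal(prospect_utility(-10, model_parameters(1, nu = 1, lam = 2)), -20)
  expect_equal(prospect_utility(0, model_parameters(1)), 0)
  # closed form at the cohort-mean curvatures
  expect_equal(prospect_utility(10, model_parameters(1, mu = 0.48)),
               exp(0.48 * log(10)))
  expect_equal(
    prospect_utility(-10, model_parameters(1, nu = 0.52, lam = 0.51)),
    -0.51 * exp(0.52 * log(10))
  )
  expect_error(model_parameters(1, lam = -1), "non-negative")
})

test_that("prospect utility is odd-symmetric at lam=1, mu=nu, and monotone", {
  for (ex in c(0.3, 0.7, 1, 1.6)) {
    p <- model_parameters(1, mu = ex, nu = ex, lam = 1)
    r <- c(1, 5, 10, 25)
    expect_equal(prospect_utility(-r, p), -prospect_utility(r, p))
  }
  p <- model_parameters(1, mu = 0.6)
  gains <- prospect_utility(1:20, p)
  expect_true(all(diff(gains) > 0))
  lams <- seq(0.1, 3, by = 0.2)
  losses <- vapply(lams, function(l) {
    prospect_utility(-10, model_parameters(1, nu = 0.8, lam = l))
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("value update follows the asymmetric rule and carries over the unchosen box", {
  p0 <- model_parameters(1, alpha_pos = 0.5, alpha_neg = 0.25, phi = 0)
  up <- update_q(c(right = 0, left = 0), "right", utility = 0, p0)
  expect_equal(up$q, c(right = 0, left = 0)) # zero update
  expect_equal(up$delta, 0)
  up <- update_q(c(right = 0, left = 3), "right", utility = 10, p0)
  expect_equal(up$q[["right"]], 5)
  expect_equal(up$q[["left"]], 3)
  p1 <- model_parameters(1, alpha_pos = 0.5, alpha_neg = 0.25, phi = 1)
  up <- update_q(c(right = 2, left = -1), "right", utility = -10, p1)
  expect_equal(up$q[["right"]], 2 + 0.25 * (-12) + 1) # = 0
  expect_equal(up$q[["left"]], -1)
  expect_equal(up$delta, -12)
  expect_error(update_q(c(right = 0, left = 0), "middle", 1, p0), "unknown")
})

test_that("softmax probabilities are uniform at beta=0, exact at known values, and overflow-safe", {
  expect_equal(choice_probabilities(c(right = 3.7, left = 3.7), beta = 2),
               c(right = 0.5, left = 0.5))
  expect_equal(choice_probabilities(c(right = 42, left = -17), beta = 0),
               c(right = 0.5, left = 0.5))
  p <- choice_probabilities(c(right = 1, left = 0), beta = 1)
  expect_equal(p[["right"]], exp(1) / (exp(1) + 1), tolerance = 1e-12)
  big <- choice_probabilities(c(right = 1e6, left = -1e6), beta = 10)
  expect_true(all(is.finite(big)))
  expect_equal(sum(big), 1)
  expect_error(choice_probabilities(c(right = Inf, left = 0), 1), "finite")
})

test_that("softmax sums to 1 and stays strictly positive over randomized values", {
  withr::with_seed(7, {
    for (i in 1:200) {
      q <- stats::runif(2, -1e6, 1e6)
      b <- stats::runif(1, 0, 5)
      p <- choice_probabilities(c(right = q[1], left = q[2]), b)
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
    for (i in 1:200) {
      q <- stats::runif(2, -100, 100)
      b <- stats::runif(1, 0, 3)
      p <- choice_probabilities(c(right = q[1], left = q[2]), b)
      expect_true(all(p > 0))
    }
  })
})

test_that("simulated sessions have the right length, and exploitation beats random choice", {
  s <- make_standard_schedule()
  p <- model_parameters(beta = 1, alpha_pos = 0.4, alpha_neg = 0.4)
  sim <- simulate_agent(p, s, seed = 1)
  expect_length(sim$record$trial, 100)
  expect_identical(nrow(sim$trace), 100L)
  expect_identical(simulate_agent(p, s, seed = 1)$record,
                   sim$record) # seeded determinism

  correct_box <- ifelse(win_probability(s, 1:100, "right") > 0.5,
                        "right", "left")
  accuracy <- function(params, seeds) {
    mean(vapply(seeds, function(k) {
      mean(simulate_agent(params, s, seed = k)$record$choice == correct_box)
    }, numeric(1)))
  }
  random_p <- model_parameters(beta = 0, alpha_pos = 0.5, alpha_neg = 0.5)
  greedy_p <- model_parameters(beta = 10, alpha_pos = 0.5, alpha_neg = 0.5)
  acc0 <- accuracy(random_p, 1:2000)
  acc10 <- accuracy(greedy_p, 2001:4000)
  expect_lt(abs(acc0 - 0.5), 0.01) # beta=0 is coin flipping
  expect_gt(acc10, acc0)
})

test_that("replaying a simulated record through update_q reproduces the trace", {
  s <- make_standard_schedule()
  p <- model_parameters(beta = 0.9, mu = 0.7, nu = 1.1, alpha_pos = 0.3,
                        alpha_neg = 0.6, lam = 1.4, phi = 0.05)
  sim <- simulate_agent(p, s, seed = 99)
  q <- c(right = 0, left = 0)
  for (t in 1:100) {
    pr <- choice_probabilities(q, p$beta)
    expect_equal(pr[["right"]], sim$trace$p_right[t], tolerance = 1e-12)
    u <- prospect_utility(sim$record$reward[t], p)
    up <- update_q(q, sim$record$choice[t], u, p)
    expect_equal(up$delta, sim$trace$delta[t], tolerance = 1e-12)
    q <- up$q
    expect_equal(q[["right"]], sim$trace$q_right_after[t], tolerance = 1e-12)
    expect_equal(q[["left"]], sim$trace$q_left_after[t], tolerance = 1e-12)
  }
})

test_that("with phi=0 the chosen value stays inside the utility hull", {
  s <- make_standard_schedule()
  withr::with_seed(31, {
    for (i in 1:20) {
      p <- model_parameters(beta = stats::runif(1, 0, 3),
                            mu = stats::runif(1, 0.2, 1.5),
                            nu = stats::runif(1, 0.2, 1.5),
                            alpha_pos = stats::runif(1),
                            alpha_neg = stats::runif(1),
                            lam = stats::runif(1, 0.2, 3), phi = 0)
      sim <- simulate_agent(p, s, seed = 5000 + i)
      u_lo <- min(prospect_utility(-10, p), 0)
      u_hi <- max(prospect_utility(10, p), 0)
      expect_true(all(sim$trace$q_right_after >= u_lo - 1e-12 &
                        sim$trace$q_right_after <= u_hi + 1e-12))
      expect_true(all(sim$trace$q_left_after >= u_lo - 1e-12 &
                        sim$trace$q_left_after <= u_hi + 1e-12))
    }
  })
})

test_that("relabeling the boxes leaves likelihood and performance unchanged", {
  s <- make_standard_schedule()
  p <- model_parameters(beta = 1.2, mu = 0.8, nu = 0.9, alpha_pos = 0.45,
                        alpha_neg = 0.55, lam = 1.3, phi = 0.2)
  sim <- simulate_agent(p, s, seed = 17)
  rec <- sim$record
  flipped <- behavioral_record(
    rec$subject_id,
    ifelse(rec$choice == "right", "left", "right"), rec$reward
  )
  expect_equal(log_likelihood(flipped, p), log_likelihood(rec, p),
               tolerance = 1e-12)
  expect_equal(tab_performance(flipped), tab_performance(rec))
})

test_that("session score is the plain reward sum", {
  expect_equal(tab_performance(
    behavioral_record("a", c("right", "left", "right"), c(10, 10, -10))), 10)
  expect_equal(tab_performance(
    behavioral_record("b", rep("right", 100), rep(10, 100))), 1000)
  expect_equal(tab_performance(
    behavioral_record("c", rep("left", 50), rep(c(10, -10), 25))), 0)
  expect_error(tab_performance(behavioral_record("d", character(), numeric())),
               "empty")
})
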