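#' Configuration of a synthetic study cohort
#'
#' Describes the study design the generator emulates: enrollment and
#' exclusion counts, per-trait generating distributions (normals
#' truncated to each trait's support), the probit coefficient vectors
#' that turn traits into binary insight-task outcomes, and the task
#' order probability.
#'
#' Each element of `trait_distributions` is `c(mean, sd, lower, upper)`;
#' draws are from the normal truncated to `[lower, upper]`. Each probit
#' coefficient vector is named: `intercept`, the seven traits,
#' `tab_performance`, and `other_success` (the cross-task transfer term,
#' applied only when the task is administered second).
#'
#' @param n_enrolled,n_incomplete,n_prior_experience enrollment and
#'   exclusion counts.
#' @param trait_distributions named list of `c(mean, sd, lower, upper)`.
#' @param probit_coefficients_8coin,probit_coefficients_9dot named
#'   coefficient vectors.
#' @param order_probability chance that the 8-coin task comes first.
#' @param schedule the [reward_schedule()] for the TAB sessions.
#' @param seed root seed of the whole cohort.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_enrolled, n_incomplete, n_prior_experience,
                          trait_distributions,
                          probit_coefficients_8coin,
                          probit_coefficients_9dot,
                          order_probability = 0.5,
                          schedule = make_standard_schedule(),
                          seed = 1) {
  if (n_incomplete + n_prior_experience > n_enrolled) {
    stop("exclusion counts exceed enrollment")
  }
  if (order_probability < 0 || order_probability > 1) {
    stop("order_probability must lie in [0, 1]")
  }
  stopifnot(setequal(names(trait_distributions), param_names()))
  need <- c("intercept", param_names(), "tab_performance", "other_success")
  for (cf in list(probit_coefficients_8coin, probit_coefficients_9dot)) {
    miss <- setdiff(need, names(cf))
    if (length(miss)) {
      stop("probit coefficients lack terms: ", paste(miss, collapse = ", "))
    }
  }
  structure(list(
    n_enrolled = as.integer(n_enrolled),
    n_incomplete = as.integer(n_incomplete),
    n_prior_experience = as.integer(n_prior_experience),
    trait_distributions = trait_distributions,
    probit_coefficients_8coin = probit_coefficients_8coin,
    probit_coefficients_9dot = probit_coefficients_9dot,
    order_probability = order_probability,
    schedule = schedule, seed = seed
  ), class = "cohort_config")
}

#' Default synthetic-study configuration
#'
#' The study conditions the pipeline emulates: 364 enrolled, 7 incomplete
#' and 32 prior-experience exclusions (325 retained), a 50/50 task order,
#' trait distributions centered on the cohort means with matching SDs
#' (truncated to each trait's support; the perseveration trait is
#' truncated to the estimable range \[-50, 50\]), and probit coefficient
#' vectors equal to the full-specification point estimates, including the
#' 0.59 cross-task transfer terms.
#'
#' @param seed root seed.
#' @return a [cohort_config()].
#' @export
default_study_config <- function(seed = 1) {
  cohort_config(
    n_enrolled = 364, n_incomplete = 7, n_prior_experience = 32,
    trait_distributions = list(
      beta      = c(0.85, 1.06, 0, Inf),
      mu        = c(0.48, 0.28, 0, Inf),
      nu        = c(0.52, 0.30, 0, Inf),
      alpha_pos = c(0.42, 0.27, 0, 1),
      alpha_neg = c(0.59, 0.29, 0, 1),
      lam       = c(0.51, 0.28, 0, Inf),
      phi       = c(-12.57, 213.86, -50, 50)
    ),
    probit_coefficients_8coin = c(
      intercept = -0.53, beta = 0.00, mu = -0.08, nu = -0.09,
      alpha_pos = 0.26, alpha_neg = -0.69, lam = -0.07, phi = 0.00,
      tab_performance = 0.00, other_success = 0.59
    ),
    probit_coefficients_9dot = c(
      intercept = 0.53, beta = 0.00, mu = -0.34, nu = 0.23,
      alpha_pos = 0.11, alpha_neg = 0.31, lam = -0.63, phi = 0.01,
      tab_performance = -0.01, other_success = 0.59
    ),
    order_probability = 0.5, seed = seed
  )
}

# inverse-CDF draws from Normal(mean, sd) truncated to [lower, upper]
rtruncnorm_inv <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi_ <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi_ - plo), mean, sd)
}

probit_linpred <- function(coefs, traits, perf, other = NULL) {
  eta <- coefs[["intercept"]] +
    as.matrix(traits[param_names()]) %*% coefs[param_names()] +
    coefs[["tab_performance"]] * perf
  if (!is.null(other)) eta <- eta + coefs[["other_success"]] * other
  drop(eta)
}

#' Generate a full synthetic cohort
#'
#' Draws each subject's latent traits from the configured truncated
#' normals, simulates one TAB session per subject with the generative
#' Q-learning model, assigns the task order by a Bernoulli draw, marks
#' the configured numbers of incomplete / prior-experience exclusions
#' uniformly at random (independent of traits), and generates binary
#' insight outcomes through probit links on the TRUE traits and TAB
#' performance — the first-administered task without, the
#' second-administered task with, the cross-task transfer term. Excluded
#' subjects carry no insight outcomes. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort_table`: `subjects` (a data.frame with
#'   true traits, `tab_performance`, `task_order`, `excluded_reason`,
#'   `success_8coin`, `success_9dot`) and `records` (named list of
#'   [behavioral_record()]s).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_enrolled
  ids <- sprintf("S%04d", seq_len(n))

  traits <- with_seed(derive_seed(config$seed, 1L), {
    as.data.frame(lapply(config$trait_distributions, function(d) {
      rtruncnorm_inv(n, d[1], d[2], d[3], d[4])
    }))
  })

  sims <- lapply(seq_len(n), function(i) {
    p <- traits[i, ]
    simulate_agent(
      model_parameters(p$beta, p$mu, p$nu, p$alpha_pos, p$alpha_neg,
                       p$lam, p$phi),
      config$schedule, seed = derive_seed(config$seed, 2L, i),
      subject_id = ids[i]
    )$record
  })
  names(sims) <- ids
  perf <- unname(vapply(sims, tab_performance, numeric(1)))

  order_first_8coin <- with_seed(
    derive_seed(config$seed, 3L),
    stats::runif(n) < config$order_probability
  )

  excluded <- rep("none", n)
  flagged <- with_seed(
    derive_seed(config$seed, 4L),
    sample.int(n, config$n_incomplete + config$n_prior_experience)
  )
  excluded[flagged[seq_len(config$n_incomplete)]] <- "incomplete"
  if (config$n_prior_experience > 0) {
    excluded[flagged[config$n_incomplete + seq_len(config$n_prior_experience)]] <-
      "prior_experience"
  }

  u <- with_seed(derive_seed(config$seed, 5L),
                 matrix(stats::runif(2 * n), ncol = 2))
  eta8_first <- probit_linpred(config$probit_coefficients_8coin, traits, perf)
  eta9_first <- probit_linpred(config$probit_coefficients_9dot, traits, perf)
  s8 <- s9 <- integer(n)
  # first-administered task: no transfer term; second: transfer from first
  s8[order_first_8coin] <-
    as.integer(u[order_first_8coin, 1] <
                 stats::pnorm(eta8_first[order_first_8coin]))
  s9[!order_first_8coin] <-
    as.integer(u[!order_first_8coin, 1] <
                 stats::pnorm(eta9_first[!order_first_8coin]))
  eta9_second <- probit_linpred(config$probit_coefficients_9dot, traits,
                                perf, other = s8)
  eta8_second <- probit_linpred(config$probit_coefficients_8coin, traits,
                                perf, other = s9)
  s9[order_first_8coin] <-
    as.integer(u[order_first_8coin, 2] <
                 stats::pnorm(eta9_second[order_first_8coin]))
  s8[!order_first_8coin] <-
    as.integer(u[!order_first_8coin, 2] <
                 stats::pnorm(eta8_second[!order_first_8coin]))
  s8[excluded != "none"] <- NA_integer_
  s9[excluded != "none"] <- NA_integer_

  subjects <- data.frame(
    subject_id = ids, traits, tab_performance = perf,
    task_order = ifelse(order_first_8coin, "8coin_first", "9dot_first"),
    excluded_reason = excluded, success_8coin = s8, success_9dot = s9,
    stringsAsFactors = FALSE
  )
  structure(list(subjects = subjects, records = sims),
            class = "cohort_table")
}

#' Drop excluded subjects
#'
#' Keeps only rows with `excluded_reason == "none"`, in both the subject
#' table and the record list.
#'
#' @param cohort a `cohort_table`.
#' @return filtered `cohort_table`; warns if nothing is retained.
#' @export
apply_exclusions <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  keep <- cohort$subjects$excluded_reason == "none"
  if (!any(keep)) warning("all subjects excluded; empty cohort")
  out <- cohort
  out$subjects <- cohort$subjects[keep, , drop = FALSE]
  rownames(out$subjects) <- NULL
  out$records <- cohort$records[cohort$subjects$subject_id[keep]]
  out
}

#' True-trait table in fitted-parameter format
#'
#' The oracle-mode counterpart of [fit_cohort()]'s output: the generating
#' traits keyed by subject, for regression recovery tests free of
#' estimation noise.
#'
#' @param cohort a `cohort_table`.
#' @return data.frame with `subject_id` and the seven traits, plus a
#'   `converged = TRUE` column so it joins like a fit table.
#' @export
true_trait_table <- function(cohort) {
  df <- cohort$subjects[, c("subject_id", param_names())]
  df$converged <- TRUE
  df
}
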