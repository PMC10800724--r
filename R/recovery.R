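#' Trait distributions used for parameter-recovery studies
#'
#' The cohort generator's trait distributions, with one change: the
#' perseveration increment `phi` is drawn from its standard-normal prior
#' instead of the cohort-level wide truncation. Under the additive update
#' rule, `|phi|` in the tens drives every choice into deterministic
#' repetition, and a session of identical choices carries no information
#' about any trait, so recovery is only meaningful with `phi` at the
#' model's own prior scale.
#'
#' @return named list of `c(mean, sd, lower, upper)` per trait.
#' @export
recovery_trait_distributions <- function() {
  d <- default_study_config()$trait_distributions
  d$phi <- c(0, 1, -Inf, Inf)
  d
}

draw_traits <- function(n, trait_distributions) {
  as.data.frame(lapply(trait_distributions, function(d) {
    rtruncnorm_inv(n, d[1], d[2], d[3], d[4])
  }))
}

#' Simulate-and-refit parameter recovery study
#'
#' Draws `n_agents` true trait vectors, simulates each agent through
#' `schedule`, re-estimates the traits by [fit_map()], and reports
#' true-vs-estimated correlations and median absolute errors per trait.
#' Attenuation is expected for the traits that enter the likelihood only
#' through the utility scale (`beta`, `mu`, `nu`, `lam`): with rewards
#' fixed at +10/-10 the data identify only the products
#' `beta * 10^mu` and `beta * lam * 10^nu`, so those traits are pinned
#' down by the prior alone and correlate imperfectly with their
#' generating values even at the exact MAP.
#'
#' @param n_agents number of simulated subjects.
#' @param schedule a [reward_schedule()]; defaults to ten tilings of the
#'   standard session (1000 trials).
#' @param trait_distributions generating distributions, as in
#'   [cohort_config()]; defaults to [recovery_trait_distributions()].
#' @param priors a [prior_spec()].
#' @param config a [fit_config()]; restart streams derive from its seed.
#' @param seed root seed for truths and sessions.
#' @return list with `agents` (data.frame of `true_*` and `est_*`
#'   columns plus fit diagnostics) and `summary` (per-trait correlation
#'   and median absolute error).
#' @export
parameter_recovery <- function(n_agents = 50,
                               schedule = tile_schedule(
                                 make_standard_schedule(), 10),
                               trait_distributions =
                                 recovery_trait_distributions(),
                               priors = prior_spec(),
                               config = fit_config(),
                               seed = 1) {
  truths <- with_seed(derive_seed(seed, 51L),
                      draw_traits(n_agents, trait_distributions))
  rows <- lapply(seq_len(n_agents), function(i) {
    tr <- truths[i, ]
    p <- model_parameters(tr$beta, tr$mu, tr$nu, tr$alpha_pos,
                          tr$alpha_neg, tr$lam, tr$phi)
    rec <- simulate_agent(p, schedule, seed = derive_seed(seed, 52L, i),
                          subject_id = sprintf("A%03d", i))$record
    cfg <- config
    cfg$seed <- derive_seed(seed, 53L, i)
    fr <- fit_map(rec, priors, cfg)
    est <- unlist(fr$theta_hat[param_names()])
    out <- data.frame(agent = i, t(unlist(tr)), t(est),
                      log_post = fr$log_posterior, converged = fr$converged)
    names(out) <- c("agent", paste0("true_", param_names()),
                    paste0("est_", param_names()), "log_post", "converged")
    out
  })
  agents <- do.call(rbind, rows)
  summary <- data.frame(
    trait = param_names(),
    correlation = vapply(param_names(), function(nm) {
      stats::cor(agents[[paste0("true_", nm)]], agents[[paste0("est_", nm)]])
    }, numeric(1)),
    median_abs_error = vapply(param_names(), function(nm) {
      stats::median(abs(agents[[paste0("true_", nm)]] -
                          agents[[paste0("est_", nm)]]))
    }, numeric(1)),
    row.names = NULL
  )
  list(agents = agents, summary = summary)
}
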