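#' The seven learning traits of one agent
#'
#' Bundles the parameters of the prospect-utility Q-learning model:
#' inverse temperature `beta` (exploitation vs exploration), gain
#' curvature `mu` (risk aversion in gains), loss curvature `nu`
#' (risk seeking in losses), asymmetric learning rates `alpha_pos` /
#' `alpha_neg` for non-negative vs negative prediction errors, loss
#' aversion `lam`, and the choice-autocorrelation control `phi` added to
#' the chosen option's value on every update.
#'
#' @param beta inverse temperature, `>= 0`.
#' @param mu gain-curvature exponent, `>= 0`.
#' @param nu loss-curvature exponent, `>= 0`.
#' @param alpha_pos learning rate for `delta >= 0`, in `[0, 1]`.
#' @param alpha_neg learning rate for `delta < 0`, in `[0, 1]`.
#' @param lam loss-aversion coefficient, `>= 0`.
#' @param phi perseveration increment, any real.
#' @return an object of class `model_parameters`.
#' @export
model_parameters <- function(beta, mu = 1, nu = 1, alpha_pos = 0.5,
                             alpha_neg = 0.5, lam = 1, phi = 0) {
  vals <- c(beta = beta, mu = mu, nu = nu, alpha_pos = alpha_pos,
            alpha_neg = alpha_neg, lam = lam, phi = phi)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  if (beta < 0 || mu < 0 || nu < 0 || lam < 0) {
    stop("beta, mu, nu and lam must be non-negative")
  }
  if (alpha_pos < 0 || alpha_pos > 1 || alpha_neg < 0 || alpha_neg > 1) {
    stop("alpha_pos and alpha_neg must lie in [0, 1]")
  }
  structure(as.list(vals), class = "model_parameters")
}

#' Names of the seven traits, in canonical order
#' @return character vector.
#' @export
param_names <- function() {
  c("beta", "mu", "nu", "alpha_pos", "alpha_neg", "lam", "phi")
}

#' Prospect utility of a reward
#'
#' Gains are curved as `reward^mu`; losses as `-lam * (-reward)^nu`, so
#' `lam > 1` weights losses more than equal gains (loss aversion) and
#' `lam < 1` less (loss taking). A zero reward maps to zero utility.
#'
#' @param reward reward in points (vectorized).
#' @param params a [model_parameters()].
#' @return utility (vector).
#' @export
#' @examples
#' prospect_utility(-10, model_parameters(1, lam = 2)) # -20
prospect_utility <- function(reward, params) {
  ifelse(reward > 0, reward^params$mu,
         ifelse(reward < 0, -params$lam * (-reward)^params$nu, 0))
}

#' One Q-learning value update
#'
#' Applies the asymmetric prediction-error update to the chosen option:
#' `delta = utility - Q[chosen]`, then `Q[chosen] += alpha_pos * delta +
#' phi` if `delta >= 0` (else `alpha_neg`); the unchosen option's value is
#' carried over unchanged.
#'
#' @param q named numeric vector `c(right = , left = )` of action values.
#' @param chosen `"right"` or `"left"`.
#' @param utility transformed reward driving the update.
#' @param params a [model_parameters()].
#' @return list with `q` (updated values), `delta`, and `q_before`.
#' @export
update_q <- function(q, chosen, utility, params) {
  if (!chosen %in% names(q)) stop("unknown box: ", chosen)
  q_before <- q
  delta <- utility - q[[chosen]]
  rate <- if (delta >= 0) params$alpha_pos else params$alpha_neg
  q[[chosen]] <- q[[chosen]] + rate * delta + params$phi
  list(q = q, delta = delta, q_before = q_before)
}

#' Softmax choice probabilities over the two boxes
#'
#' `P(i) = exp(beta * Q_i) / sum_j exp(beta * Q_j)`, computed with the
#' max subtracted before exponentiation so large `beta * Q` cannot
#' overflow. At `beta = 0` choice is uniform.
#'
#' @param q named numeric vector of action values.
#' @param beta inverse temperature, `>= 0`.
#' @return named probability vector summing to 1.
#' @export
#' @examples
#' choice_probabilities(c(right = 1, left = 0), beta = 1)
choice_probabilities <- function(q, beta) {
  if (any(!is.finite(q))) stop("non-finite action values")
  if (beta < 0) stop("beta must be non-negative")
  x <- beta * q
  e <- exp(x - max(x))
  e / sum(e)
}

#' One subject's trial sequence
#'
#' @param subject_id identifier.
#' @param choice character vector of `"right"`/`"left"`, one per trial.
#' @param reward numeric vector of obtained points.
#' @return object of class `behavioral_record` with 1-based trial indices.
#' @export
behavioral_record <- function(subject_id, choice, reward) {
  stopifnot(length(choice) == length(reward),
            all(choice %in% c("right", "left")))
  structure(
    list(subject_id = subject_id, trial = seq_along(choice),
         choice = choice, reward = as.numeric(reward)),
    class = "behavioral_record"
  )
}

#' @export
length.behavioral_record <- function(x) length(x$trial)

#' Simulate one agent through a bandit session
#'
#' Runs the generative model forward: per trial, sample the choice by
#' inverse CDF on the softmax probabilities, draw the chosen box's reward
#' from the schedule, transform it through [prospect_utility()] and update
#' the chosen value. One uniform pair is pre-assigned per trial position
#' from the session seed, so the draw consumed at trial t never depends on
#' how earlier draws were used.
#'
#' @param params a [model_parameters()].
#' @param schedule a [reward_schedule()].
#' @param seed session seed.
#' @param subject_id identifier stored on the record.
#' @return list with `record` (a [behavioral_record()]) and `trace`, a
#'   data.frame with per-trial `utility`, `delta`, `p_right`, and the
#'   Q-value snapshots before and after each update.
#' @export
simulate_agent <- function(params, schedule, seed, subject_id = "agent") {
  stopifnot(inherits(params, "model_parameters"),
            inherits(schedule, "reward_schedule"))
  prof <- win_probability_profile(schedule)
  n <- schedule$n_trials
  u <- with_seed(derive_seed(seed, 101L), stats::runif(2L * n))
  sim <- simulate_qlearn_cpp(
    params$beta, params$mu, params$nu, params$alpha_pos, params$alpha_neg,
    params$lam, params$phi, prof$right, prof$left,
    schedule$reward_win, schedule$reward_loss,
    u[seq_len(n)], u[n + seq_len(n)]
  )
  choice <- ifelse(sim$choice == 1L, "right", "left")
  list(
    record = behavioral_record(subject_id, choice, sim$reward),
    trace = data.frame(
      trial = seq_len(n), utility = sim$utility, delta = sim$delta,
      p_right = sim$p_right,
      q_right_before = sim$q_right_before, q_left_before = sim$q_left_before,
      q_right_after = sim$q_right_after, q_left_after = sim$q_left_after
    )
  )
}

#' Total points earned in a session
#'
#' The session score the study analyzes ("TAB performance"): the sum of
#' obtained rewards over all trials.
#'
#' @param record a [behavioral_record()].
#' @return total points.
#' @export
tab_performance <- function(record) {
  if (length(record) == 0) stop("empty behavioral record")
  sum(record$reward)
}
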