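#' Reward schedule for a two-armed bandit session
#'
#' A `reward_schedule` describes the block structure of per-box win
#' probabilities and the two reward magnitudes of a TAB session. Blocks are
#' 1-based inclusive trial ranges and must tile `[1, n_trials]` exactly.
#'
#' @param n_trials number of choices in the session.
#' @param blocks data.frame with columns `first_trial`, `last_trial`,
#'   `p_win_right`, `p_win_left`.
#' @param reward_win points awarded on a win.
#' @param reward_loss points awarded on a loss; must be `< reward_win`.
#' @return an object of class `reward_schedule`.
#' @export
reward_schedule <- function(n_trials, blocks, reward_win = 10,
                            reward_loss = -10) {
  stopifnot(is.data.frame(blocks),
            all(c("first_trial", "last_trial", "p_win_right",
                  "p_win_left") %in% names(blocks)))
  if (!(reward_win > reward_loss)) {
    stop("reward_win must exceed reward_loss")
  }
  blocks <- blocks[order(blocks$first_trial), , drop = FALSE]
  covered <- unlist(Map(seq, blocks$first_trial, blocks$last_trial))
  if (!identical(as.integer(sort(covered)), seq_len(n_trials))) {
    stop("blocks must tile [1, n_trials] with no gaps or overlaps")
  }
  p <- c(blocks$p_win_right, blocks$p_win_left)
  if (any(p < 0 | p > 1)) stop("win probabilities must lie in [0, 1]")
  structure(
    list(n_trials = as.integer(n_trials), blocks = blocks,
         reward_win = reward_win, reward_loss = reward_loss),
    class = "reward_schedule"
  )
}

#' Standard 100-trial reversal schedule
#'
#' The session design used throughout: 100 choices, rewards +10/-10, the
#' right box winning with probability 0.7 on trials 1-30, 0.3 on trials
#' 31-70 (first reversal), and 0.7 again on trials 71-100 (second
#' reversal); the left box is complementary.
#'
#' @return a [reward_schedule()].
#' @export
#' @examples
#' sched <- make_standard_schedule()
#' win_probability(sched, 30, "right") # 0.7
#' win_probability(sched, 31, "right") # 0.3
make_standard_schedule <- function() {
  reward_schedule(
    n_trials = 100,
    blocks = data.frame(
      first_trial = c(1L, 31L, 71L),
      last_trial  = c(30L, 70L, 100L),
      p_win_right = c(0.7, 0.3, 0.7),
      p_win_left  = c(0.3, 0.7, 0.3)
    ),
    reward_win = 10, reward_loss = -10
  )
}

#' Tile a schedule's block structure over more trials
#'
#' Repeats a schedule end to end `times` times, preserving the reversal
#' structure; used for long sessions in parameter-recovery simulations.
#'
#' @param schedule a [reward_schedule()].
#' @param times number of repetitions.
#' @return a [reward_schedule()] with `times * n_trials` trials.
#' @export
tile_schedule <- function(schedule, times) {
  stopifnot(inherits(schedule, "reward_schedule"), times >= 1)
  b <- schedule$blocks
  reps <- lapply(seq_len(times) - 1L, function(k) {
    off <- k * schedule$n_trials
    data.frame(first_trial = b$first_trial + off,
               last_trial = b$last_trial + off,
               p_win_right = b$p_win_right, p_win_left = b$p_win_left)
  })
  reward_schedule(schedule$n_trials * as.integer(times),
                  do.call(rbind, reps),
                  schedule$reward_win, schedule$reward_loss)
}

#' Write a reward schedule as a plain-text config block
#'
#' Header lines (`n_trials`, `reward_win`, `reward_loss`) followed by one
#' `block:` line per block with its trial range and the two win
#' probabilities. Round-trips through [read_schedule()].
#'
#' @param schedule a [reward_schedule()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  lines <- c(
    sprintf("n_trials: %d", schedule$n_trials),
    sprintf("reward_win: %.17g", schedule$reward_win),
    sprintf("reward_loss: %.17g", schedule$reward_loss),
    sprintf("block: %d %d %.17g %.17g",
            schedule$blocks$first_trial, schedule$blocks$last_trial,
            schedule$blocks$p_win_right, schedule$blocks$p_win_left)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a reward schedule written by [write_schedule()]
#' @param path input file.
#' @return a [reward_schedule()].
#' @export
read_schedule <- function(path) {
  lines <- readLines(path)
  val <- function(key) {
    m <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(m) != 1) stop("schedule config lacks field: ", key)
    as.numeric(sub(paste0("^", key, ": *"), "", m))
  }
  bl <- grep("^block:", lines, value = TRUE)
  if (!length(bl)) stop("schedule config lacks blocks")
  mat <- do.call(rbind, lapply(strsplit(sub("^block: *", "", bl), " +"),
                               as.numeric))
  reward_schedule(
    n_trials = val("n_trials"),
    blocks = data.frame(first_trial = as.integer(mat[, 1]),
                        last_trial = as.integer(mat[, 2]),
                        p_win_right = mat[, 3], p_win_left = mat[, 4]),
    reward_win = val("reward_win"), reward_loss = val("reward_loss")
  )
}

block_index <- function(schedule, trial) {
  if (any(trial < 1 | trial > schedule$n_trials)) {
    stop("trial out of range [1, ", schedule$n_trials, "]")
  }
  findInterval(trial, schedule$blocks$first_trial)
}

#' Block-local win probability of a box
#'
#' @param schedule a [reward_schedule()].
#' @param trial 1-based trial index (vectorized).
#' @param box `"right"` or `"left"`.
#' @return win probability (vector).
#' @export
win_probability <- function(schedule, trial, box = c("right", "left")) {
  box <- match.arg(box)
  i <- block_index(schedule, trial)
  if (box == "right") schedule$blocks$p_win_right[i]
  else schedule$blocks$p_win_left[i]
}

#' Per-trial win probability vectors for both boxes
#' @param schedule a [reward_schedule()].
#' @return list with numeric vectors `right` and `left` of length `n_trials`.
#' @export
win_probability_profile <- function(schedule) {
  tr <- seq_len(schedule$n_trials)
  list(right = win_probability(schedule, tr, "right"),
       left = win_probability(schedule, tr, "left"))
}

#' Draw the reward for choosing a box on a trial
#'
#' Returns `reward_win` with the box's block-local win probability, else
#' `reward_loss`. Each (session seed, trial, box) triple uses its own
#' derived substream, so repeated or probe draws are independent of draws
#' at other trials and reproducible under the same seed.
#'
#' @param schedule a [reward_schedule()].
#' @param trial 1-based trial index (vectorized).
#' @param box `"right"` or `"left"`.
#' @param seed session seed.
#' @return reward points (vector).
#' @export
draw_reward <- function(schedule, trial, box = c("right", "left"), seed) {
  box <- match.arg(box)
  p <- win_probability(schedule, trial, box)
  u <- vapply(seq_along(trial), function(k) {
    with_seed(derive_seed(seed, trial[k], if (box == "right") 1L else 2L),
              stats::runif(1))
  }, numeric(1))
  ifelse(u < p, schedule$reward_win, schedule$reward_loss)
}
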