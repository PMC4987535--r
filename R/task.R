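#' Task configuration for the two-stage decision task
#'
#' Collects the design constants of the two-stage Markov decision task:
#' session length, the sampling range of the per-trial common-transition
#' probability, and the reflected Gaussian walk governing the four
#' second-stage reward probabilities.
#'
#' Defaults encode the standard design: 150 trials per condition; on every
#' trial each first-stage symbol's common-transition probability is drawn
#' independently from Uniform(0.4, 1), giving a long-run mean of 0.7; reward
#' probabilities drift in [0.25, 0.75] by Gaussian steps with sd 0.025,
#' reflected at the bounds.
#'
#' @param n_trials Number of trials in a session (default 150).
#' @param common_prob_mean Long-run mean of the common-transition
#'   probability (default 0.7); used as the reference point for colour
#'   deviations.
#' @param transition_prob_low,transition_prob_high Support of the per-trial
#'   common-transition probability (defaults 0.4, 1.0).
#' @param reward_prob_low,reward_prob_high Reflecting bounds of the reward
#'   probability walks (defaults 0.25, 0.75).
#' @param reward_walk_sd Standard deviation of a single Gaussian walk step
#'   (default 0.025).
#' @param condition Experimental condition, 1 (no cue) or 2 (colour-bar
#'   cues shown).
#' @param seed Optional integer seed recorded in the config and used by
#'   [generate_session()] when set.
#' @return An object of class `task_config` (a named list).
#' @examples
#' cfg <- task_config(n_trials = 10, condition = 1)
#' @export
task_config <- function(n_trials = 150L,
                        common_prob_mean = 0.7,
                        transition_prob_low = 0.4,
                        transition_prob_high = 1.0,
                        reward_prob_low = 0.25,
                        reward_prob_high = 0.75,
                        reward_walk_sd = 0.025,
                        condition = 1L,
                        seed = NULL) {
  cfg <- list(
    n_trials = as.integer(n_trials),
    common_prob_mean = common_prob_mean,
    transition_prob_low = transition_prob_low,
    transition_prob_high = transition_prob_high,
    reward_prob_low = reward_prob_low,
    reward_prob_high = reward_prob_high,
    reward_walk_sd = reward_walk_sd,
    condition = as.integer(condition),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(
    cfg$n_trials >= 1L,
    cfg$transition_prob_low >= 0, cfg$transition_prob_high <= 1,
    cfg$transition_prob_low < cfg$transition_prob_high ||
      (cfg$transition_prob_low == cfg$transition_prob_high),
    cfg$reward_prob_low >= 0, cfg$reward_prob_high <= 1,
    cfg$reward_prob_low < cfg$reward_prob_high,
    cfg$reward_walk_sd >= 0,
    cfg$condition %in% c(1L, 2L)
  )
  invisible(cfg)
}

#' Default first-stage symbol-to-state map
#'
#' Each first-stage symbol has a "common" second-stage state it usually
#' leads to; the two symbols map to different states. The default maps
#' symbol A to the blue state and symbol B to the purple state.
#'
#' @param A,B Common state of each symbol, `"blue"` or `"purple"`.
#' @return Named character vector of length 2 (a bijection onto the states).
#' @export
symbol_map <- function(A = "blue", B = "purple") {
  m <- c(A = match.arg(A, STATES), B = match.arg(B, STATES))
  if (m[["A"]] == m[["B"]]) stop("symbol_map must be a bijection: the two symbols must map to different states")
  m
}

#' Sample per-trial common-transition probabilities
#'
#' Draws one common-transition probability per first-stage symbol,
#' independently and uniformly from
#' `[transition_prob_low, transition_prob_high]` (default Uniform(0.4, 1),
#' mean 0.7).
#'
#' @param config A [task_config()].
#' @return Named numeric vector `c(A = , B = )`.
#' @export
sample_transition_probs <- function(config) {
  p <- runif(2L, config$transition_prob_low, config$transition_prob_high)
  names(p) <- SYMBOLS
  p
}

# Reflect x into [lo, hi]; handles steps larger than the interval.
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  y <- ifelse(y > width, 2 * width - y, y)
  lo + y
}

#' Advance the reward-probability random walks by one step
#'
#' Each of the four second-stage reward probabilities is perturbed by an
#' independent Gaussian step (mean 0, sd `reward_walk_sd`) and mapped back
#' into `[reward_prob_low, reward_prob_high]` by reflection at the bounds.
#'
#' @param current Numeric vector of reward probabilities, all within the
#'   configured range.
#' @param config A [task_config()].
#' @return Updated probabilities, same length and names as `current`.
#' @export
step_reward_walk <- function(current, config) {
  lo <- config$reward_prob_low
  hi <- config$reward_prob_high
  if (any(current < lo - 1e-12) || any(current > hi + 1e-12)) {
    stop("reward probabilities outside configured range [", lo, ", ", hi, "]")
  }
  if (config$reward_walk_sd == 0) return(current)
  step <- rnorm(length(current), mean = 0, sd = config$reward_walk_sd)
  reflect_into(current + step, lo, hi)
}

#' Resolve a first-stage transition
#'
#' Given the chosen symbol and this trial's common-transition
#' probabilities, samples the second-stage state: the symbol's common state
#' with probability `p_common[a1]`, otherwise the other state.
#'
#' @param a1 Chosen first-stage symbol, `"A"` or `"B"`.
#' @param p_common Named probability vector from
#'   [sample_transition_probs()].
#' @param map A [symbol_map()].
#' @return List with `s2` (state name) and `transition_type`
#'   (`"common"` or `"rare"`).
#' @export
resolve_transition <- function(a1, p_common, map = symbol_map()) {
  stopifnot(a1 %in% SYMBOLS)
  common_state <- map[[a1]]
  other_state <- setdiff(STATES, common_state)
  if (runif(1L) < p_common[[a1]]) {
    list(s2 = common_state, transition_type = "common")
  } else {
    list(s2 = other_state, transition_type = "rare")
  }
}

#' Colour deviation of a trial's transition probability
#'
#' The signed deviation of a symbol's common-transition probability on the
#' current trial from its long-run mean. In the cued condition this value
#' is conveyed by the blue/purple share of the symbol's colour bar: a trial
#' probability of 0.4 with mean 0.7 gives a deviation of -0.3 (full
#' rare-colour bar), while a probability equal to the mean gives 0
#' (half/half bar).
#'
#' @param p_trial Trial transition probability (or vector thereof).
#' @param mean Long-run mean transition probability (default 0.7).
#' @return `p_trial - mean`.
#' @examples
#' colour_deviation(0.4) # -0.3
#' colour_deviation(0.7) #  0
#' @export
colour_deviation <- function(p_trial, mean = 0.7) {
  p_trial - mean
}

#' Generate a two-stage task session
#'
#' Runs `n_trials` trials of the task against a policy object. Per trial:
#' common-transition probabilities are re-sampled, the reward walks are
#' advanced (from trial 2 on), the policy chooses a first-stage symbol, the
#' transition is resolved, the policy chooses a second-stage symbol and a
#' Bernoulli reward is drawn from the current reward probability. Colour
#' deviations are generated in both conditions (they are simply not shown
#' to subjects in condition 1); the `condition` column records which.
#'
#' @param config A [task_config()].
#' @param policy A policy as returned by [uniform_policy()] or
#'   [agent_policy()]: a list with functions
#'   `choose_stage1(info)`, `choose_stage2(s2, info)`, and optionally
#'   `observe(record)`.
#' @param map A [symbol_map()].
#' @param reward_probs_init Optional numeric vector of 4 starting reward
#'   probabilities named `rprob_blue0, rprob_blue1, rprob_purple0,
#'   rprob_purple1`; drawn from Uniform(reward range) when `NULL`.
#' @param subject_id Subject identifier recorded in the output.
#' @param seed Optional seed; defaults to `config$seed`. When non-`NULL`
#'   the session is reproducible.
#' @return A `data.frame` with one row per trial and columns
#'   `subject_id, condition, trial, a1, p_common_A, p_common_B, s2,
#'   transition_type, a2, reward, colour_dev_A, colour_dev_B, rprob_blue0,
#'   rprob_blue1, rprob_purple0, rprob_purple1`.
#' @export
generate_session <- function(config, policy = uniform_policy(),
                             map = symbol_map(),
                             reward_probs_init = NULL,
                             subject_id = 1L, seed = config$seed) {
  validate_task_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  rp_names <- c("rprob_blue0", "rprob_blue1", "rprob_purple0", "rprob_purple1")
  if (is.null(reward_probs_init)) {
    rp <- runif(4L, config$reward_prob_low, config$reward_prob_high)
  } else {
    stopifnot(length(reward_probs_init) == 4L)
    rp <- as.numeric(reward_probs_init)
  }
  names(rp) <- rp_names

  out <- data.frame(
    subject_id = rep(subject_id, n), condition = rep(config$condition, n),
    trial = seq_len(n), a1 = character(n), p_common_A = numeric(n),
    p_common_B = numeric(n), s2 = character(n),
    transition_type = character(n), a2 = integer(n), reward = integer(n),
    colour_dev_A = numeric(n), colour_dev_B = numeric(n),
    rprob_blue0 = numeric(n), rprob_blue1 = numeric(n),
    rprob_purple0 = numeric(n), rprob_purple1 = numeric(n),
    stringsAsFactors = FALSE
  )

  for (t in seq_len(n)) {
    if (t > 1L) rp <- step_reward_walk(rp, config)
    p_common <- sample_transition_probs(config)
    cdev <- colour_deviation(p_common, config$common_prob_mean)
    info <- list(
      trial = t, condition = config$condition,
      colour_dev = if (config$condition == 2L) cdev else NULL,
      p_common = p_common
    )
    rec <- tryCatch({
      a1 <- policy$choose_stage1(info)
      stopifnot(a1 %in% SYMBOLS)
      trans <- resolve_transition(a1, p_common, map)
      a2 <- policy$choose_stage2(trans$s2, info)
      stopifnot(a2 %in% c(0L, 1L))
      pr <- rp[[paste0("rprob_", trans$s2, a2)]]
      r <- rbinom(1L, 1L, pr)
      list(a1 = a1, s2 = trans$s2, transition_type = trans$transition_type,
           a2 = as.integer(a2), reward = as.integer(r))
    }, error = function(e) {
      stop("policy error at trial ", t, ": ", conditionMessage(e))
    })

    out$a1[t] <- rec$a1
    out$p_common_A[t] <- p_common[["A"]]
    out$p_common_B[t] <- p_common[["B"]]
    out$s2[t] <- rec$s2
    out$transition_type[t] <- rec$transition_type
    out$a2[t] <- rec$a2
    out$reward[t] <- rec$reward
    out$colour_dev_A[t] <- cdev[["A"]]
    out$colour_dev_B[t] <- cdev[["B"]]
    out[t, rp_names] <- rp

    if (!is.null(policy$observe)) {
      policy$observe(list(
        trial = t, a1 = rec$a1, s2 = rec$s2, a2 = rec$a2, r = rec$reward,
        colour_dev = cdev
      ))
    }
  }
  out
}

#' A policy that chooses uniformly at random
#'
#' @return A policy list usable with [generate_session()].
#' @export
uniform_policy <- function() {
  list(
    choose_stage1 = function(info) sample(SYMBOLS, 1L),
    choose_stage2 = function(s2, info) sample(c(0L, 1L), 1L),
    observe = NULL
  )
}
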