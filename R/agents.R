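#' Hybrid-learner parameters
#'
#' Free parameters of the hybrid model-free / model-based learner:
#' learning rate `alpha`, inverse temperature `beta`, eligibility trace
#' `lambda`, first-stage choice stickiness `p_stick` (a logit-scale bonus
#' for repeating the previous first-stage choice), model-based weight `w`,
#' and — in the cued condition only — the colour-cue weight `v`. With
#' `w = 1` the learner is purely model-based, with `w = 0` purely
#' model-free; in condition 2 the residual model-free weight is
#' `1 - w - v`.
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Inverse temperature, non-negative.
#' @param lambda Eligibility trace in \[0, 1\].
#' @param p_stick Stickiness (unbounded real, logit units).
#' @param w Model-based weight in \[0, 1\].
#' @param v Colour-cue weight in \[0, 1\] (condition 2); `w + v <= 1`.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(alpha, beta, lambda, p_stick, w, v = 0) {
  p <- list(alpha = alpha, beta = beta, lambda = lambda,
            p_stick = p_stick, w = w, v = v)
  stopifnot(
    alpha >= 0, alpha <= 1, beta >= 0, lambda >= 0, lambda <= 1,
    w >= 0, w <= 1, v >= 0, v <= 1, w + v <= 1 + 1e-12
  )
  class(p) <- "agent_params"
  p
}

#' Initial learner state
#'
#' Q-values start at zero; transition counts start at zero (the
#' Beta-Binomial posterior then equals the uniform-prior mean 0.5);
#' there is no previous choice, so the stickiness term is 0 on trial 1.
#'
#' @return An object of class `learner_state`: `q2` (2x2 matrix,
#'   states x within-state symbols), `q1_mf` (length-2 vector over
#'   first-stage symbols), `n_trans` (2x2 matrix of symbol x state
#'   transition counts), `prev_a1` (previous first-stage choice or `NA`).
#' @export
learner_state <- function() {
  st <- list(
    q2 = matrix(0, 2, 2, dimnames = list(STATES, c("0", "1"))),
    q1_mf = c(A = 0, B = 0),
    n_trans = matrix(0L, 2, 2, dimnames = list(SYMBOLS, STATES)),
    prev_a1 = NA_character_
  )
  class(st) <- "learner_state"
  st
}

#' Second-stage model-free update
#'
#' Delta rule on the chosen second-stage symbol's value:
#' `q2 <- q2 + alpha * (r - q2)`, where `r - q2` is the reward prediction
#' error. Other entries are untouched.
#'
#' @param state A [learner_state()].
#' @param s2 Second-stage state (`"blue"`/`"purple"`).
#' @param a2 Within-state symbol index, 0 or 1.
#' @param r Reward, 0 or 1.
#' @param params An [agent_params()].
#' @return Updated state.
#' @export
update_stage2 <- function(state, s2, a2, r, params) {
  j <- a2 + 1L
  q <- state$q2[s2, j]
  state$q2[s2, j] <- q + params$alpha * (r - q)
  state
}

#' First-stage model-free (SARSA-lambda) update
#'
#' Updates the chosen first-stage symbol's model-free value with two
#' prediction errors, both computed from the pre-update second-stage
#' value: the state-value error `q2(s2, a2) - q1_mf(a1)` and, scaled by
#' the eligibility trace `lambda`, the reward prediction error
#' `r - q2(s2, a2)`. Call before [update_stage2()] within a trial.
#'
#' @inheritParams update_stage2
#' @param a1 First-stage symbol chosen (`"A"`/`"B"`).
#' @return Updated state.
#' @export
update_stage1_mf <- function(state, a1, s2, a2, r, params) {
  q2 <- state$q2[s2, a2 + 1L]
  q1 <- state$q1_mf[[a1]]
  state$q1_mf[[a1]] <- q1 + params$alpha * (q2 - q1) +
    params$alpha * params$lambda * (r - q2)
  state
}

#' Beta-Binomial posterior transition probability
#'
#' Posterior-mean probability that a first-stage symbol leads to the blue
#' state, under a uniform Beta(1, 1) prior over its transition
#' probability: `(n_blue + 1) / (n_blue + n_purple + 2)`.
#'
#' @param n_blue,n_purple Observed transition counts (non-negative).
#' @return Posterior mean P(blue); P(purple) is its complement.
#' @export
transition_posterior <- function(n_blue, n_purple) {
  stopifnot(all(n_blue >= 0), all(n_purple >= 0))
  (n_blue + 1) / (n_blue + n_purple + 2)
}

#' Model-based first-stage action value
#'
#' Forward-looking value of a first-stage symbol: the expectation over
#' second-stage states of the best second-stage value, using the learner's
#' empirical (Beta-Binomial posterior) transition probabilities:
#' `Q_MB(a) = P(blue|a) max_j q2(blue, j) + P(purple|a) max_j q2(purple, j)`.
#'
#' @param state A [learner_state()].
#' @param a1 First-stage symbol.
#' @return Scalar model-based value.
#' @export
model_based_q <- function(state, a1) {
  p_blue <- transition_posterior(state$n_trans[a1, "blue"],
                                 state$n_trans[a1, "purple"])
  p_blue * max(state$q2["blue", ]) + (1 - p_blue) * max(state$q2["purple", ])
}

#' Hybrid first-stage action value
#'
#' Condition 1: the convex combination
#' `Q = w * Q_MB + (1 - w) * Q_MF`.
#'
#' Condition 2 adds an additive correction for the on-screen colour cue:
#' `Q = w * Q_MB + v * dQ + (1 - w - v) * Q_MF` with
#' `dQ = colour_dev(a1) * (max q2(common state of a1) - max q2(other state))`.
#' With this form, weighting the cue equally to the learned base
#' probability (`v = w`) recovers the fully informed model-based value
#' evaluated at probability (posterior mean + deviation).
#'
#' @inheritParams model_based_q
#' @param params An [agent_params()].
#' @param condition 1 or 2.
#' @param colour_dev Named vector of per-symbol colour deviations
#'   (required for condition 2).
#' @param map A [symbol_map()].
#' @return Scalar hybrid value.
#' @export
hybrid_q <- function(state, a1, params, condition = 1L, colour_dev = NULL,
                     map = symbol_map()) {
  qmb <- model_based_q(state, a1)
  qmf <- state$q1_mf[[a1]]
  if (condition == 1L) {
    return(params$w * qmb + (1 - params$w) * qmf)
  }
  if (is.null(colour_dev)) {
    stop("condition-2 hybrid value requires colour_dev")
  }
  common_state <- map[[a1]]
  other_state <- setdiff(STATES, common_state)
  dq <- colour_dev[[a1]] *
    (max(state$q2[common_state, ]) - max(state$q2[other_state, ]))
  params$w * qmb + params$v * dq + (1 - params$w - params$v) * qmf
}

# Numerically safe softmax over a vector of logits.
softmax <- function(x) {
  z <- x - max(x)
  e <- exp(z)
  e / sum(e)
}

#' First-stage choice probabilities
#'
#' Logit choice over the two first-stage symbols:
#' `P(a) propto exp(beta * Q(a) + p_stick * 1(a == prev_a1))`. The
#' stickiness bonus enters the exponent unscaled by `beta` (logit units)
#' and is zero when there is no previous trial.
#'
#' @param qA,qB Hybrid values of symbols A and B.
#' @param prev_a1 Previous first-stage choice (`"A"`, `"B"`, or `NA`).
#' @param params An [agent_params()].
#' @return Named probability vector `c(A = , B = )`, summing to 1.
#' @export
choice_prob_stage1 <- function(qA, qB, prev_a1, params) {
  stick <- c(A = 0, B = 0)
  if (!is.na(prev_a1)) stick[[prev_a1]] <- params$p_stick
  x <- params$beta * c(A = qA, B = qB) + stick
  softmax(x)
}

#' Second-stage choice probabilities
#'
#' Softmax with inverse temperature `beta` over the two second-stage
#' values of the reached state; no stickiness at this stage.
#'
#' @param q2_state Numeric vector of the 2 second-stage values.
#' @param params An [agent_params()].
#' @return Probability vector of length 2 (symbol indices 0, 1).
#' @export
choice_prob_stage2 <- function(q2_state, params) {
  softmax(params$beta * q2_state)
}

#' Learning-agent policy for [generate_session()]
#'
#' Wraps a hybrid learner into the stateful policy interface: choices are
#' sampled from the model's stage-1 and stage-2 choice probabilities
#' computed from the pre-trial state; after each trial the state is
#' updated in order (first-stage SARSA-lambda update, then second-stage
#' update, both with the pre-update `q2`; then the transition count).
#' The policy records a Q-trace of model-free, model-based and hybrid
#' values at each choice.
#'
#' @param params An [agent_params()].
#' @param condition 1 or 2.
#' @param map A [symbol_map()].
#' @param init_state Optional [learner_state()] to start from (e.g. to
#'   carry transition counts across conditions).
#' @return A policy list; the accumulated trace is available via
#'   `policy$q_trace()` and the final state via `policy$state()`.
#' @export
agent_policy <- function(params, condition = 1L, map = symbol_map(),
                         init_state = NULL) {
  st <- if (is.null(init_state)) learner_state() else init_state
  trace <- list()
  env <- environment()

  choose_stage1 <- function(info) {
    cd <- if (condition == 2L) info$colour_dev else NULL
    qA_mb <- model_based_q(st, "A")
    qB_mb <- model_based_q(st, "B")
    qA <- hybrid_q(st, "A", params, condition, cd, map)
    qB <- hybrid_q(st, "B", params, condition, cd, map)
    env$trace[[length(trace) + 1L]] <- data.frame(
      trial = info$trial, qA_mf = st$q1_mf[["A"]], qB_mf = st$q1_mf[["B"]],
      qA_mb = qA_mb, qB_mb = qB_mb, qA_hybrid = qA, qB_hybrid = qB
    )
    pr <- choice_prob_stage1(qA, qB, st$prev_a1, params)
    SYMBOLS[1L + (runif(1L) >= pr[["A"]])]
  }

  choose_stage2 <- function(s2, info) {
    pr <- choice_prob_stage2(st$q2[s2, ], params)
    as.integer(runif(1L) >= pr[1L])
  }

  observe <- function(rec) {
    s <- env$st
    s <- update_stage1_mf(s, rec$a1, rec$s2, rec$a2, rec$r, params)
    s <- update_stage2(s, rec$s2, rec$a2, rec$r, params)
    s$n_trans[rec$a1, rec$s2] <- s$n_trans[rec$a1, rec$s2] + 1L
    s$prev_a1 <- rec$a1
    env$st <- s
    invisible(NULL)
  }

  list(
    choose_stage1 = choose_stage1,
    choose_stage2 = choose_stage2,
    observe = observe,
    q_trace = function() do.call(rbind, env$trace),
    state = function() env$st
  )
}

#' Simulate a hybrid agent through a full session
#'
#' Rolls a learner through [generate_session()] and returns the trial
#' table together with the per-trial Q-trace (pre-choice model-free,
#' model-based and hybrid values for both symbols) and the final learner
#' state.
#'
#' @param params An [agent_params()].
#' @param config A [task_config()].
#' @param map A [symbol_map()].
#' @param init_state Optional starting [learner_state()].
#' @param subject_id Recorded in the output tables.
#' @param seed Optional seed (defaults to `config$seed`).
#' @return List with elements `trials`, `q_trace`, `state`.
#' @export
simulate_agent <- function(params, config, map = symbol_map(),
                           init_state = NULL, subject_id = 1L,
                           seed = config$seed) {
  pol <- agent_policy(params, config$condition, map, init_state)
  trials <- generate_session(config, pol, map, subject_id = subject_id,
                             seed = seed)
  list(trials = trials, q_trace = pol$q_trace(), state = pol$state())
}
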