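test_that("second-stage delta rule follows the hand-iterated values", {
  p <- agent_params(0.5, 1, 0.5, 0, 0.5)
  st <- learner_state()
  st <- update_stage2(st, "blue", 1L, 1, p)
  expect_equal(unname(st$q2["blue", 2]), 0.5)
  expect_equal(unname(st$q2["blue", 1]), 0) # other entries untouched
  expect_equal(unname(st$q2["purple", 1]), 0)

  # alpha = 0 freezes values
  p0 <- agent_params(0, 1, 0.5, 0, 0.5)
  expect_equal(update_stage2(learner_state(), "purple", 0L, 1, p0)$q2,
               learner_state()$q2)

  # rewards 1, 1, 0 at alpha = 0.3: 0.3, 0.51, 0.357
  p3 <- agent_params(0.3, 1, 0.5, 0, 0.5)
  st <- learner_state()
  got <- numeric(3)
  for (i in seq_along(c(1, 1, 0))) {
    st <- update_stage2(st, "blue", 0L, c(1, 1, 0)[i], p3)
    got[i] <- unname(st$q2["blue", 1])
  }
  expect_equal(got, c(0.3, 0.51, 0.357))
})

test_that("first-stage SARSA-lambda update combines both prediction errors", {
  # lambda = 0: only the state-value error; hand-computed single step
  st <- learner_state()
  st$q2["blue", 1] <- 0.6
  st$q1_mf[["A"]] <- 0.2
  p <- agent_params(0.5, 1, 0, 0, 0.5)
  st2 <- update_stage1_mf(st, "A", "blue", 0L, 1, p)
  expect_equal(st2$q1_mf[["A"]], 0.4)
  expect_equal(st2$q1_mf[["B"]], 0)

  # lambda = 1 collapses algebraically to a delta rule on the reward
  set.seed(31)
  for (i in 1:10) {
    st <- learner_state()
    st$q2["purple", 2] <- runif(1)
    st$q1_mf[["B"]] <- runif(1)
    r <- sample(0:1, 1)
    a <- runif(1)
    p1 <- agent_params(a, 1, 1, 0, 0.5)
    got <- update_stage1_mf(st, "B", "purple", 1L, r, p1)$q1_mf[["B"]]
    expect_equal(got, st$q1_mf[["B"]] + a * (r - st$q1_mf[["B"]]))
  }

  # alpha = 0 leaves the value untouched
  p0 <- agent_params(0, 1, 0.7, 0, 0.5)
  expect_equal(update_stage1_mf(st, "A", "blue", 0L, 1, p0)$q1_mf,
               st$q1_mf)
})

test_that("Beta-Binomial posterior matches the conjugate closed form", {
  expect_equal(transition_posterior(0, 0), 0.5)
  expect_equal(transition_posterior(6, 2), 0.7)
  for (k in c(1, 5, 40)) expect_equal(transition_posterior(k, k), 0.5)
  # complement structure
  expect_equal(transition_posterior(3, 9) + transition_posterior(9, 3), 1)
})

test_that("model-based value is the posterior-weighted best state value", {
  st <- learner_state()
  st$q2[] <- 0.4
  expect_equal(model_based_q(st, "A"), 0.4) # constant values
  expect_equal(model_based_q(st, "B"), 0.4)

  st <- learner_state()
  st$q2["blue", ] <- c(1, 0.2)
  st$n_trans["A", ] <- c(6L, 2L) # posterior P(blue|A) = 0.7
  expect_equal(model_based_q(st, "A"), 0.7 * 1 + 0.3 * 0)

  st$n_trans["A", ] <- c(10000L, 0L) # effectively deterministic
  expect_equal(model_based_q(st, "A"), max(st$q2["blue", ]),
               tolerance = 1e-3)
})

test_that("hybrid value interpolates and the cue correction is coherent", {
  st <- learner_state()
  st$q2["blue", ] <- c(0.9, 0.1)
  st$q2["purple", ] <- c(0.3, 0.2)
  st$q1_mf[] <- c(0.6, 0.25)
  st$n_trans["A", ] <- c(5L, 1L)

  pure_mb <- agent_params(0.5, 1, 0.5, 0, 1)
  pure_mf <- agent_params(0.5, 1, 0.5, 0, 0)
  expect_equal(hybrid_q(st, "A", pure_mb), model_based_q(st, "A"))
  expect_equal(hybrid_q(st, "A", pure_mf), st$q1_mf[["A"]])

  # condition 2 with w = v: equals (1-w-v) Q_MF + w Q_MB evaluated at
  # the shifted probability (posterior mean + colour deviation)
  w <- 0.3
  pars <- agent_params(0.5, 1, 0.5, 0, w, w)
  cd <- c(A = 0.2, B = -0.1)
  got <- hybrid_q(st, "A", pars, condition = 2L, colour_dev = cd)
  p_shift <- transition_posterior(5, 1) + cd[["A"]]
  q_shift <- p_shift * max(st$q2["blue", ]) +
    (1 - p_shift) * max(st$q2["purple", ])
  expect_equal(got, (1 - 2 * w) * st$q1_mf[["A"]] + w * q_shift)

  expect_error(hybrid_q(st, "A", pars, condition = 2L), "colour_dev")
})

test_that("choice probabilities are softmax with stickiness, log-sum-exp safe", {
  flat <- agent_params(0.5, 0, 0.5, 0, 0.5)
  expect_equal(unname(choice_prob_stage1(3, -1, NA, flat)), c(0.5, 0.5))

  unit <- agent_params(0.5, 1, 0.5, 0, 0.5)
  pr <- choice_prob_stage1(1, 0, NA, unit)
  expect_equal(pr[["A"]], 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(sum(pr), 1)

  sticky <- agent_params(0.5, 1, 0.5, 50, 0.5)
  expect_equal(choice_prob_stage1(0.5, 0.5, "B", sticky)[["B"]], 1,
               tolerance = 1e-12)

  # stage 2
  expect_equal(choice_prob_stage2(c(0.4, 0.4), unit), c(0.5, 0.5))
  two <- agent_params(0.5, 2, 0.5, 0, 0.5)
  expect_equal(choice_prob_stage2(c(1, 0.5), two)[1], 1 / (1 + exp(-1)))
  hot <- agent_params(0.5, 1e6, 0.5, 0, 0.5)
  pr <- choice_prob_stage2(c(0.8, 0.2), hot)
  expect_true(all(is.finite(pr)) && sum(pr) == 1)
  expect_equal(pr[1], 1)
})

test_that("simulated Q-values stay in [0, 1] and model invariances hold", {
  set.seed(32)
  for (i in 1:5) {
    cond <- sample(1:2, 1)
    pars <- random_params(cond)
    sim <- simulate_agent(pars, task_config(n_trials = 80, condition = cond,
                                            seed = 100 + i))
    qt <- sim$q_trace
    # learner values are bounded; the condition-2 hybrid can leave [0, 1]
    # through the signed cue correction, so test it for condition 1 only
    cols <- c("qA_mf", "qB_mf", "qA_mb", "qB_mb",
              if (cond == 1L) c("qA_hybrid", "qB_hybrid"))
    expect_true(all(qt[, cols] >= -1e-12 & qt[, cols] <= 1 + 1e-12))
  }

  # with w = 1 the likelihood is invariant to lambda
  trials <- random_trials(60)
  nll_a <- negative_log_likelihood(agent_params(0.4, 3, 0.1, 0.3, 1),
                                   trials, 1)
  nll_b <- negative_log_likelihood(agent_params(0.4, 3, 0.9, 0.3, 1),
                                   trials, 1)
  expect_equal(nll_a, nll_b, tolerance = 1e-12)

  # condition-2 model with v = 0 reproduces condition 1 exactly
  trials2 <- random_trials(60, condition = 2L)
  pars <- agent_params(0.35, 4, 0.6, -0.2, 0.55, 0)
  expect_equal(negative_log_likelihood(pars, trials2, 2),
               negative_log_likelihood(pars, trials2, 1),
               tolerance = 1e-12)

  # alpha = 0, beta = 0: i.i.d. uniform choices
  sim <- simulate_agent(agent_params(0, 0, 0, 0, 0.5),
                        task_config(n_trials = 2000, seed = 9))
  expect_equal(mean(sim$trials$a1 == "A"), 0.5, tolerance = 0.05)
})

test_that("pure strategies produce their stay signatures", {
  set.seed(33)
  cfg <- task_config(n_trials = 150)
  # model-free agent: stay after reward regardless of transition
  mf <- simulate_agent(agent_params(0.6, 6, 0.9, 0, 0), cfg, seed = 41)
  rows <- build_stay_design(mf$trials, 1)
  tab <- stay_probability_table(rows)
  p_rew <- mean(tab$p_stay[tab$reward_prev == 1])
  p_un <- mean(tab$p_stay[tab$reward_prev == 0])
  expect_gt(p_rew, p_un)

  # model-based agent: reward x transition interaction
  mb_tabs <- lapply(1:8, function(i) {
    sim <- simulate_agent(agent_params(0.6, 6, 0.5, 0, 1), cfg,
                          seed = 50 + i)
    stay_probability_table(build_stay_design(sim$trials, 1))
  })
  cell <- function(tab, r, c) tab$p_stay[tab$reward_prev == r &
                                           tab$common_prev == c]
  inter <- vapply(mb_tabs, function(tab) {
    (cell(tab, 1, 1) - cell(tab, 1, 0)) - (cell(tab, 0, 1) - cell(tab, 0, 0))
  }, numeric(1))
  expect_gt(mean(inter), 0)
})
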