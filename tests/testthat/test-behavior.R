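test_that("stay design encodes previous-trial outcomes and colour difference", {
  trials <- make_trials(
    a1 = c("A", "A", "B"), s2 = c("blue", "purple", "purple"),
    a2 = c(0, 1, 0), reward = c(1, 0, 1),
    colour_dev_A = c(0.1, 0.2, -0.05),
    colour_dev_B = c(-0.2, 0.1, 0.15),
    condition = 2L
  )
  rows <- build_stay_design(trials, 2L)
  expect_identical(nrow(rows), 2L) # trial 1 contributes no row
  expect_identical(rows$stay, c(1L, 0L))
  expect_identical(rows$reward_prev, c(1L, 0L))
  expect_identical(rows$common_prev, c(1L, 0L)) # A->blue common, A->purple rare
  # symbol A (common blue) chosen at t-1; current bars: blue share of A
  # = +0.2, blue share of B = -(+0.1) -> difference 0.3
  expect_equal(rows$colour_diff[1], 0.3)

  # condition-1 design is the condition-2 design minus the colour term
  rows1 <- build_stay_design(trials, 1L)
  expect_identical(setdiff(names(rows), names(rows1)), "colour_diff")

  # an agent that always repeats: all stay = 1
  rep_trials <- make_trials(a1 = rep("B", 6), s2 = rep("purple", 6),
                            a2 = rep(0, 6), reward = rep(0, 6))
  expect_true(all(build_stay_design(rep_trials, 1L)$stay == 1L))
})

test_that("stay table aggregates subjects first and flags empty cells", {
  rows <- rbind(
    data.frame(subject_id = 1L, trial = 2:7, stay = c(1L, 1L, 1L, 1L, 0L, 1L),
               reward_prev = c(1L, 1L, 1L, 1L, 0L, 0L),
               common_prev = c(1L, 1L, 0L, 0L, 1L, 1L)),
    data.frame(subject_id = 2L, trial = 2:3, stay = c(0L, 1L),
               reward_prev = c(1L, 0L), common_prev = c(1L, 0L))
  )
  tab <- stay_probability_table(rows)
  # subject-first aggregation: cell (1,1) = mean(mean(1,1), mean(0)) = 0.5,
  # not the pooled 2/3
  expect_equal(tab$p_stay[tab$reward_prev == 1 & tab$common_prev == 1], 0.5)
  # cell (0,0): only subject 2 contributes
  expect_equal(tab$p_stay[tab$reward_prev == 0 & tab$common_prev == 0], 1)

  # deterministic stayers: every populated cell is exactly 1
  det <- data.frame(subject_id = rep(1:3, each = 4), trial = rep(2:5, 3),
                    stay = 1L, reward_prev = rep(c(0L, 1L), 6),
                    common_prev = rep(c(0L, 0L, 1L, 1L), 3))
  expect_true(all(stay_probability_table(det)$p_stay == 1))

  # empty cell flagged NA, not zero
  sub <- rows[rows$reward_prev == 1 & rows$common_prev == 1, ]
  tab2 <- stay_probability_table(sub)
  expect_true(is.na(tab2$p_stay[tab2$reward_prev == 0 &
                                  tab2$common_prev == 0]))
  expect_identical(tab2$n_subjects[tab2$reward_prev == 0 &
                                     tab2$common_prev == 0], 0L)
})

# Simulate stay rows directly from a known logistic generator,
# independent of the agent machinery.
logistic_stay_rows <- function(n_subj, n_rows, b0, b_r, b_c, b_rc) {
  do.call(rbind, lapply(seq_len(n_subj), function(s) {
    r <- sample(0:1, n_rows, replace = TRUE)
    cm <- sample(0:1, n_rows, replace = TRUE)
    eta <- b0 + b_r * r + b_c * cm + b_rc * r * cm
    data.frame(subject_id = s, trial = seq_len(n_rows) + 1L,
               stay = rbinom(n_rows, 1, plogis(eta)),
               reward_prev = r, common_prev = cm)
  }))
}

test_that("group regression recovers a known logistic generator", {
  set.seed(51)
  # pure reward effect
  rows <- logistic_stay_rows(25, 140, b0 = 0.2, b_r = 1, b_c = 0, b_rc = 0)
  fit <- fit_stay_regression(rows)
  g <- fit$group
  rew <- g[g$term == "reward_prev", ]
  expect_gt(rew$mean, 0)
  expect_lt(rew$p, 0.05)
  inter <- g[g$term == "reward_prev:common_prev", ]
  expect_gt(inter$p, 0.05) # no interaction in the generator
  # slope recovery within 20%
  expect_lt(abs(rew$mean - 1) / 1, 0.2)

  # null generator: no term significant at a strict level
  rows0 <- logistic_stay_rows(25, 140, 0, 0, 0, 0)
  g0 <- fit_stay_regression(rows0)$group
  expect_true(all(g0$p > 0.005))
  expect_true(all(abs(g0$mean) < 0.15))
})

test_that("separated subjects are flagged and excluded from the group test", {
  set.seed(52)
  rows <- logistic_stay_rows(6, 60, 0.2, 0.8, 0, 0)
  # one deterministic stayer: perfectly separated fit
  det <- data.frame(subject_id = 99L, trial = 2:41, stay = 1L,
                    reward_prev = sample(0:1, 40, TRUE),
                    common_prev = sample(0:1, 40, TRUE))
  expect_warning(fit <- fit_stay_regression(rbind(rows, det)), "separation")
  expect_identical(fit$n_subjects, 6L)
  expect_identical(fit$excluded, "99")
})

test_that("condition-2 agents dominated by the cue show the triple interaction", {
  set.seed(53)
  cfg <- task_config(n_trials = 150, condition = 2L)
  rows <- do.call(rbind, lapply(1:12, function(i) {
    sim <- simulate_agent(agent_params(0.6, 8, 0.5, 0, 0.1, 0.8), cfg,
                          subject_id = i, seed = 500 + i)
    build_stay_design(sim$trials, 2L)
  }))
  # separation can occur for individual near-deterministic subjects
  fit <- suppressWarnings(fit_stay_regression(rows))
  tri <- fit$group[fit$group$term == "reward_prev:common_prev:colour_diff", ]
  expect_gt(tri$mean, 0)
  expect_lt(tri$p, 0.05)
})

test_that("choice/gaze design encodes gaze variables and filters", {
  trials <- make_trials(a1 = c("A", "A", "B", "A"),
                        s2 = rep("blue", 4), a2 = rep(0, 4),
                        reward = rep(1, 4))
  gaze_stats <- data.frame(
    subject_id = 1L, trial = 1:4,
    n_gazes = c(2L, 2L, 1L, 3L),
    first_symbol = c("B", "B", "A", "A"),
    last_symbol = c("A", "A", "A", "B"),
    dwell_A = c(300, 250, 400, 500), dwell_B = c(200, 300, 0, 450),
    last_dwell_ms = c(150, 200, 400, 300),
    dwell_advantage_last = c(100, -50, 400, -50),
    n_middle = c(0L, 0L, 0L, 1L),
    middle_dwell_mean = c(NA, NA, NA, 350),
    n_symbols_viewed = c(2L, 2L, 1L, 2L)
  )
  q <- data.frame(subject_id = 1L, trial = 1:4,
                  qA_hybrid = c(0.5, 0.6, 0.4, 0.3),
                  qB_hybrid = c(0.2, 0.4, 0.5, 0.6))
  w_tab <- data.frame(subject_id = c(1L, 2L), w = c(0.8, 0.1))

  d <- build_choice_gaze_design(trials, gaze_stats, q, w_tab, "two_plus")
  # trial 1 dropped (no previous trial), trial 3 dropped (one gaze)
  expect_identical(d$trial, c(2L, 4L))
  # trial 2: gazes [B, A], A chosen
  t2 <- d[d$trial == 2L, ]
  expect_identical(t2$first_gaze_B, 1L)
  expect_identical(t2$last_gaze_B, 0L)
  expect_identical(t2$chose_B, 0L)
  expect_identical(t2$prev_B, 0L)
  expect_equal(t2$q_diff, -0.2)
  expect_identical(t2$group, 1L) # w = 0.8 above the median split

  # exactly-two filter: both symbols seen once
  d2 <- build_choice_gaze_design(trials, gaze_stats, q, w_tab, "exactly_two")
  expect_identical(d2$trial, 2L)
})
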