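# Hand-constructable trial tables and random instances for tests.

# Build a trial table from parallel vectors; colour deviations default
# to zero (condition-1 style).
make_trials <- function(a1, s2, a2, reward,
                        colour_dev_A = 0, colour_dev_B = 0,
                        subject_id = 1L, condition = 1L) {
  n <- length(a1)
  data.frame(
    subject_id = subject_id, condition = condition, trial = seq_len(n),
    a1 = a1, p_common_A = 0.7, p_common_B = 0.7, s2 = s2,
    transition_type = ifelse(
      (a1 == "A" & s2 == "blue") | (a1 == "B" & s2 == "purple"),
      "common", "rare"),
    a2 = as.integer(a2), reward = as.integer(reward),
    colour_dev_A = rep_len(colour_dev_A, n),
    colour_dev_B = rep_len(colour_dev_B, n),
    rprob_blue0 = 0.5, rprob_blue1 = 0.5,
    rprob_purple0 = 0.5, rprob_purple1 = 0.5,
    stringsAsFactors = FALSE
  )
}

# Random trial history (choices need not be model-consistent: the
# likelihood must replay any observed history).
random_trials <- function(n, condition = 1L) {
  make_trials(
    a1 = sample(c("A", "B"), n, replace = TRUE),
    s2 = sample(c("blue", "purple"), n, replace = TRUE),
    a2 = sample(0:1, n, replace = TRUE),
    reward = sample(0:1, n, replace = TRUE),
    colour_dev_A = round(runif(n, -0.3, 0.3), 3),
    colour_dev_B = round(runif(n, -0.3, 0.3), 3),
    condition = condition
  )
}

random_params <- function(condition = 1L) {
  w <- runif(1)
  v <- if (condition == 2L) runif(1, 0, 1 - w) else 0
  agent_params(alpha = runif(1), beta = runif(1, 0, 10),
               lambda = runif(1), p_stick = rnorm(1), w = w, v = v)
}

# Random gaze-event stream for fuzz tests: k events in sequence with
# random ROIs, gaps and dwells.
random_events <- function(k, subject_id = 1L, trial = 1L) {
  rois <- sample(c("left_symbol", "right_symbol", "left_bar", "right_bar"),
                 k, replace = TRUE)
  dwell <- runif(k, 30, 600)
  gap <- runif(k, 0, 200)
  onset <- cumsum(gap) + cumsum(c(0, dwell[-k]))
  data.frame(subject_id = subject_id, trial = trial, roi = rois,
             onset_ms = onset, offset_ms = onset + dwell,
             dwell_ms = dwell, stringsAsFactors = FALSE)
}

# Shared fixture: simulate gaze for n subjects of one process and return
# per-trial first-gaze-on-best rows joined with |dQ|.
simulate_process_gaze <- function(process, n_subj, n_trials = 120,
                                  seed = 80) {
  set.seed(seed)
  specs <- sample_subject_specs(n_subj)
  specs$gaze_process <- process
  cfg <- task_config(n_trials = n_trials, condition = 1L)
  do.call(rbind, lapply(seq_len(n_subj), function(i) {
    spec <- specs[i, ]
    spec$subject_id <- i
    sim <- generate_choices(spec, cfg)
    g <- generate_gaze(spec, sim$trials, sim$q_trace)
    st <- gaze_statistics(clean_events(g$events), g$side_map)
    qt <- sim$q_trace
    qt$best <- ifelse(qt$qB_hybrid >= qt$qA_hybrid, "B", "A")
    qt$adq <- abs(qt$qB_hybrid - qt$qA_hybrid)
    m <- merge(st, cbind(subject_id = i, qt), by = c("subject_id", "trial"))
    m <- merge(m, sim$trials[, c("subject_id", "trial", "a1")],
               by = c("subject_id", "trial"))
    m$first_on_best <- as.integer(m$first_symbol == m$best)
    m
  }))
}


# Per-subject contrast of first-gaze-on-best between hard (low |dQ|) and
# easy (high |dQ|) trials: a bounded, stable summary of whether the first
# gaze tracks the Q-value difference.
first_gaze_value_contrast <- function(df) {
  vapply(split(df, df$subject_id), function(d) {
    hi <- d$adq > median(d$adq)
    if (!any(hi) || all(hi)) return(NA_real_)
    mean(d$first_on_best[hi]) - mean(d$first_on_best[!hi])
  }, numeric(1))
}
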