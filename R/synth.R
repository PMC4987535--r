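#' Priors for synthetic subject parameters
#'
#' Documented priors from which synthetic subjects' learning parameters
#' are drawn: `alpha`, `lambda`, `w` ~ Uniform(0, 1) (so the model-based
#' weight spans the full range observed empirically); `beta` ~
#' LogNormal(log 5, 0.5), centring the inverse temperature on values
#' typical of fits in this task family; `p_stick` ~ Normal(0, 1). The
#' condition-2 weight pair `(w, v)` is drawn uniformly on the simplex
#' `w, v >= 0, w + v <= 1`.
#'
#' @param beta_meanlog,beta_sdlog Log-normal parameters for `beta`.
#' @param p_stick_sd Normal sd for stickiness.
#' @return List of prior settings.
#' @export
subject_priors <- function(beta_meanlog = log(5), beta_sdlog = 0.5,
                           p_stick_sd = 1) {
  list(beta_meanlog = beta_meanlog, beta_sdlog = beta_sdlog,
       p_stick_sd = p_stick_sd)
}

#' Gaze-generator configuration
#'
#' Parameters of the two descriptive gaze-generating processes. They are
#' pattern generators, not a fitted sequential-sampling model: the
#' `comparison` process emulates the signatures of a value-comparison
#' (aDDM-like) process - first gaze side independent of values, mostly
#' two or more alternating gazes, middle dwells shrinking as the choice
#' gets easier, choice biased toward the last-seen and longer-seen symbol
#' - while the `search` process emulates directed visual search: the
#' first gaze lands on the to-be-chosen symbol with probability
#' increasing in the Q-value difference, single-gaze trials are common,
#' and dwell advantage matters little.
#'
#' @param mean_dwell_ms Median middle-gaze dwell at Q-difference 0.
#' @param dwell_sdlog Log-scale dwell dispersion.
#' @param first_last_frac First/last dwells are this fraction of
#'   `mean_dwell_ms` on the log scale.
#' @param comparison,search Per-process parameter lists:
#'   `p_single` (single-gaze probability; for `search` the probability of
#'   stopping after a first gaze that found the intended symbol),
#'   `last_bias` (P(last gaze on the chosen symbol) in multi-gaze
#'   trials), `dwell_boost` (multiplier on the chosen symbol's dwells,
#'   creating the dwell-advantage choice effect), `value_sens` (log-scale
#'   shrinkage of middle dwells per unit |Q-difference|),
#'   `extra_gaze_p` (geometric continuation parameter for gazes beyond
#'   two), and for `search` the first-gaze logit `first_b0 + first_b1 *
#'   |dQ|` of landing on the to-be-chosen symbol.
#' @param no_gaze_rate Fraction of trials with no on-ROI gaze (excluded
#'   downstream); default 20/150.
#' @param bar_share_b0,bar_share_w,bar_share_v Condition-2 bar-attention
#'   target share `b0 + bw * w + bv * v`, coupling bar gaze to the
#'   ground-truth model-based and cue weights.
#' @param gap_range_ms Inter-gaze (saccade) gap range.
#' @param fixation_ms Forced central fixation block duration at trial
#'   start (samples only; outside all ROIs).
#' @return List of class `gaze_config`.
#' @export
gaze_config <- function(mean_dwell_ms = 500, dwell_sdlog = 0.4,
                        first_last_frac = 0.8,
                        comparison = list(p_single = 0.32, last_bias = 0.78,
                                          dwell_boost = 1.35,
                                          value_sens = 0.8,
                                          extra_gaze_p = 0.45),
                        search = list(p_single = 0.75, last_bias = 0.9,
                                      dwell_boost = 1.05, value_sens = 0.3,
                                      extra_gaze_p = 0.8,
                                      first_b0 = 0.3, first_b1 = 2.5),
                        no_gaze_rate = 20 / 150,
                        bar_share_b0 = 0.5, bar_share_w = 0.2,
                        bar_share_v = 0.15,
                        gap_range_ms = c(20, 60), fixation_ms = 300) {
  structure(list(mean_dwell_ms = mean_dwell_ms, dwell_sdlog = dwell_sdlog,
                 first_last_frac = first_last_frac,
                 comparison = comparison, search = search,
                 no_gaze_rate = no_gaze_rate,
                 bar_share_b0 = bar_share_b0, bar_share_w = bar_share_w,
                 bar_share_v = bar_share_v,
                 gap_range_ms = gap_range_ms, fixation_ms = fixation_ms),
            class = "gaze_config")
}

#' Draw synthetic subject specifications
#'
#' Samples per-subject learning parameters from [subject_priors()] and
#' assigns each subject a gaze-generating process. The default
#' assignment rule ties the process to the ground-truth strategy:
#' subjects with `w < 0.5` use the `comparison` process, the rest the
#' `search` process.
#'
#' @param n Number of subjects.
#' @param priors A [subject_priors()] list.
#' @param process_rule Function mapping the subject-spec `data.frame` to a
#'   character vector of processes (`"comparison"`/`"search"`).
#' @param seed Optional seed.
#' @return `data.frame` with one row per subject: `subject_id, alpha,
#'   beta, lambda, p_stick, w` (condition-1 weight), `w2, v2`
#'   (condition-2 simplex weights), `gaze_process`.
#' @export
sample_subject_specs <- function(n, priors = subject_priors(),
                                 process_rule = NULL, seed = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  # uniform on the simplex {w2, v2 >= 0, w2 + v2 <= 1} via sorted uniforms
  u1 <- runif(n)
  u2 <- runif(n)
  lo <- pmin(u1, u2)
  hi <- pmax(u1, u2)
  specs <- data.frame(
    subject_id = seq_len(n),
    alpha = runif(n),
    beta = rlnorm(n, priors$beta_meanlog, priors$beta_sdlog),
    lambda = runif(n),
    p_stick = rnorm(n, 0, priors$p_stick_sd),
    w = runif(n),
    w2 = lo,
    v2 = hi - lo
  )
  specs$gaze_process <- if (is.null(process_rule)) {
    ifelse(specs$w < 0.5, "comparison", "search")
  } else {
    process_rule(specs)
  }
  specs
}

spec_params <- function(spec, condition) {
  if (condition == 1L) {
    agent_params(spec$alpha, spec$beta, spec$lambda, spec$p_stick, spec$w)
  } else {
    agent_params(spec$alpha, spec$beta, spec$lambda, spec$p_stick,
                 spec$w2, spec$v2)
  }
}

#' Simulate a synthetic subject's choices
#'
#' Delegates to [simulate_agent()] with the subject spec's parameters for the
#' configured condition (condition 2 uses the simplex weights
#' `(w2, v2)`).
#'
#' @param spec One row of [sample_subject_specs()].
#' @param config A [task_config()].
#' @param map A [symbol_map()].
#' @param init_state Optional starting [learner_state()].
#' @param seed Optional seed.
#' @return As [simulate_agent()]: list with `trials`, `q_trace`, `state`.
#' @export
generate_choices <- function(spec, config, map = symbol_map(),
                             init_state = NULL, seed = NULL) {
  simulate_agent(spec_params(spec, config$condition), config, map,
                 init_state, subject_id = spec$subject_id, seed = seed)
}

# Build a strictly alternating symbol sequence of length n starting at
# `first`.
alternate_seq <- function(first, n) {
  other <- if (first == "A") "B" else "A"
  rep(c(first, other), length.out = n)
}

# Symbol gaze sequence for one trial under the comparison process:
# first gaze uniform (independent of values), last gaze biased toward
# the chosen symbol, strict alternation in between (the sequence length
# absorbs the parity constraint).
comparison_sequence <- function(chosen, pp) {
  if (runif(1) < pp$p_single) {
    return(sample(SYMBOLS, 1L))
  }
  first <- sample(SYMBOLS, 1L)
  other <- if (chosen == "A") "B" else "A"
  last <- if (runif(1) < pp$last_bias) chosen else other
  n <- 2L + stats::rgeom(1L, pp$extra_gaze_p)
  need_odd <- first == last
  if ((n %% 2L == 1L) != need_odd) n <- n + 1L
  alternate_seq(first, n)
}

# Search process: first gaze lands on the to-be-chosen symbol with
# probability increasing in |dQ|; if it did, the trial usually ends
# after that single gaze, otherwise a short confirmation sequence ends
# on the chosen symbol.
search_sequence <- function(chosen, adq, pp) {
  other <- if (chosen == "A") "B" else "A"
  on_chosen <- runif(1) < plogis(pp$first_b0 + pp$first_b1 * adq)
  first <- if (on_chosen) chosen else other
  if (on_chosen) {
    if (runif(1) < pp$p_single) return(first)
    return(c(chosen, other, chosen))
  }
  if (runif(1) < pp$last_bias) c(first, chosen) else c(first)
}

# Dwell times for a symbol sequence: first/last gazes shorter on
# average; middle dwells shrink with |dQ| (easier choices); the chosen
# symbol's dwells are inflated by the process's dwell_boost.
sequence_dwells <- function(seq_syms, chosen, adq, cfg, pp) {
  n <- length(seq_syms)
  mu <- rep(log(cfg$mean_dwell_ms * cfg$first_last_frac), n)
  if (n >= 3L) {
    mu[2:(n - 1L)] <- log(cfg$mean_dwell_ms) - pp$value_sens * adq
  }
  d <- rlnorm(n, mu, cfg$dwell_sdlog)
  d[seq_syms == chosen] <- d[seq_syms == chosen] * pp$dwell_boost
  d
}

# Insert condition-2 bar gazes into a symbol gaze sequence so that the
# trial's bar dwell share approximates `share`.
add_bar_gazes <- function(rois, dwells, share) {
  if (share <= 0) return(list(rois = rois, dwells = dwells))
  total_sym <- sum(dwells)
  bar_total <- share / (1 - share) * total_sym
  n_bar <- 1L + stats::rpois(1L, 0.8)
  bar_d <- rlnorm(n_bar, log(bar_total / n_bar), 0.25)
  bar_d <- bar_d * bar_total / sum(bar_d)
  bar_side <- sample(c("left_bar", "right_bar"), n_bar, replace = TRUE)
  pos <- sort(sample.int(length(rois) + 1L, n_bar, replace = TRUE))
  out_r <- character(0)
  out_d <- numeric(0)
  k <- 1L
  for (i in seq_len(length(rois) + 1L)) {
    while (k <= n_bar && pos[k] == i) {
      out_r <- c(out_r, bar_side[k])
      out_d <- c(out_d, bar_d[k])
      k <- k + 1L
    }
    if (i <= length(rois)) {
      out_r <- c(out_r, rois[i])
      out_d <- c(out_d, dwells[i])
    }
  }
  # collapse accidental same-ROI neighbours (bars inserted side by side)
  keep_r <- character(0)
  keep_d <- numeric(0)
  for (i in seq_along(out_r)) {
    m <- length(keep_r)
    if (m > 0L && keep_r[m] == out_r[i]) {
      keep_d[m] <- keep_d[m] + out_d[i]
    } else {
      keep_r <- c(keep_r, out_r[i])
      keep_d <- c(keep_d, out_d[i])
    }
  }
  list(rois = keep_r, dwells = keep_d)
}

#' Generate synthetic gaze events for a simulated session
#'
#' Produces per-trial gaze-event streams with the statistical structure
#' assumed by the gaze analyses, driven by the subject's
#' [gaze_config()] process and the trial-by-trial hybrid Q-values of the
#' generating agent. Symbol screen sides are randomized per trial and
#' returned as a side map. A configurable fraction of trials has no
#' on-ROI gaze at all (these are later excluded by the pipeline). In
#' condition 2, bar gazes are interleaved so that the subject's bar
#' dwell share increases with the ground-truth weights.
#'
#' @param spec One row of [sample_subject_specs()].
#' @param trials Trial table from [generate_choices()].
#' @param q_trace Matching Q-trace (`qA_hybrid`, `qB_hybrid` are used).
#' @param config A [gaze_config()].
#' @param seed Optional seed.
#' @return List with `events` (`subject_id, trial, roi, onset_ms,
#'   offset_ms, dwell_ms`) and `side_map`
#'   (`subject_id, trial, left_symbol`).
#' @export
generate_gaze <- function(spec, trials, q_trace, config = gaze_config(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pp <- config[[spec$gaze_process]]
  condition <- trials$condition[1L]
  bar_share <- if (condition == 2L) {
    min(0.9, max(0, config$bar_share_b0 + config$bar_share_w * spec$w +
                   config$bar_share_v * spec$v2))
  } else 0
  n <- nrow(trials)
  side_map <- data.frame(subject_id = trials$subject_id,
                         trial = trials$trial,
                         left_symbol = sample(SYMBOLS, n, replace = TRUE),
                         stringsAsFactors = FALSE)
  ev_list <- vector("list", n)
  for (t in seq_len(n)) {
    if (runif(1) < config$no_gaze_rate) next
    chosen <- trials$a1[t]
    adq <- abs(q_trace$qB_hybrid[t] - q_trace$qA_hybrid[t])
    seq_syms <- if (spec$gaze_process == "comparison") {
      comparison_sequence(chosen, pp)
    } else {
      search_sequence(chosen, adq, pp)
    }
    left <- side_map$left_symbol[t]
    rois <- ifelse(seq_syms == left, "left_symbol", "right_symbol")
    dwells <- sequence_dwells(seq_syms, chosen, adq, config, pp)
    if (condition == 2L) {
      wb <- add_bar_gazes(rois, dwells, bar_share)
      rois <- wb$rois
      dwells <- wb$dwells
    }
    gaps <- runif(length(rois), config$gap_range_ms[1],
                  config$gap_range_ms[2])
    onset <- config$fixation_ms + cumsum(gaps) +
      cumsum(c(0, dwells[-length(dwells)]))
    ev_list[[t]] <- data.frame(
      subject_id = trials$subject_id[t], trial = trials$trial[t],
      roi = rois, onset_ms = onset, offset_ms = onset + dwells,
      dwell_ms = dwells, stringsAsFactors = FALSE
    )
  }
  events <- do.call(rbind, c(ev_list, list(make.row.names = FALSE)))
  if (is.null(events)) {
    events <- data.frame(subject_id = integer(0), trial = integer(0),
                         roi = character(0), onset_ms = numeric(0),
                         offset_ms = numeric(0), dwell_ms = numeric(0))
  }
  list(events = events, side_map = side_map)
}

#' Rasterize gaze events into 1000 Hz samples
#'
#' Converts an event stream into raw gaze samples: each trial starts
#' with a forced central-fixation block at screen centre (outside all
#' ROIs), events produce one sample per millisecond at the ROI centre
#' with Gaussian jitter, and inter-event gaps produce no samples (as
#' when the tracker loses the pupil during saccades or blinks).
#'
#' @param events Gaze events for one or more trials.
#' @param geometry A [screen_geometry()].
#' @param jitter_px Sd of positional jitter; kept small relative to the
#'   ROI margin.
#' @param fixation_ms Duration of the central fixation block.
#' @return `data.frame(subject_id, trial, t_ms, x_px, y_px)`.
#' @export
rasterize_events <- function(events, geometry = screen_geometry(),
                             jitter_px = 10, fixation_ms = 300) {
  r <- geometry$rois
  centres <- data.frame(roi = r$roi, cx = (r$x0 + r$x1) / 2,
                        cy = (r$y0 + r$y1) / 2)
  parts <- split(events, list(events$subject_id, events$trial), drop = TRUE)
  rows <- lapply(parts, function(df) {
    df <- df[order(df$onset_ms), ]
    t_fix <- seq_len(fixation_ms) - 1
    fix <- data.frame(subject_id = df$subject_id[1L], trial = df$trial[1L],
                      t_ms = t_fix,
                      x_px = geometry$screen_w / 2 +
                        rnorm(fixation_ms, 0, jitter_px),
                      y_px = geometry$screen_h / 2 +
                        rnorm(fixation_ms, 0, jitter_px))
    evs <- lapply(seq_len(nrow(df)), function(i) {
      tt <- seq(floor(df$onset_ms[i]), ceiling(df$offset_ms[i]) - 1)
      ctr <- centres[centres$roi == df$roi[i], ]
      data.frame(subject_id = df$subject_id[1L], trial = df$trial[1L],
                 t_ms = tt,
                 x_px = ctr$cx + rnorm(length(tt), 0, jitter_px),
                 y_px = ctr$cy + rnorm(length(tt), 0, jitter_px))
    })
    do.call(rbind, c(list(fix), evs))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study
#'
#' End-to-end dataset emulating the full experiment: `n_subjects`
#' synthetic subjects, each completing a condition-1 and a condition-2
#' session of 150 trials. Between conditions the learner's Q-values are
#' re-initialized (reward probabilities are reset in the task) but the
#' transition counts and the previous-choice memory persist (the symbols
#' keep their transition structure). Gaze-event streams are generated
#' for both conditions from the subject's assigned process.
#'
#' @param n_subjects Number of subjects (default 43).
#' @param config1,config2 [task_config()]s for the two conditions.
#' @param priors A [subject_priors()].
#' @param gaze_cfg A [gaze_config()].
#' @param seed Master seed; all per-subject randomness derives from it.
#' @return An object of class `synthetic_study`: `specs` (ground-truth
#'   parameter table), `trials`, `q_traces`, `gaze_events`, `side_map`,
#'   and a `manifest` recording seed and priors.
#' @export
generate_study <- function(n_subjects = 43L,
                           config1 = task_config(condition = 1L),
                           config2 = task_config(condition = 2L),
                           priors = subject_priors(),
                           gaze_cfg = gaze_config(), seed = 1L) {
  set.seed(seed)
  specs <- sample_subject_specs(n_subjects, priors)
  trials <- list()
  traces <- list()
  gaze <- list()
  sides <- list()
  for (i in seq_len(n_subjects)) {
    spec <- specs[i, ]
    sim1 <- generate_choices(spec, config1)
    carry <- learner_state()
    carry$n_trans <- sim1$state$n_trans
    carry$prev_a1 <- sim1$state$prev_a1
    sim2 <- generate_choices(spec, config2, init_state = carry)
    g1 <- generate_gaze(spec, sim1$trials, sim1$q_trace, gaze_cfg)
    g2 <- generate_gaze(spec, sim2$trials, sim2$q_trace, gaze_cfg)
    trials[[i]] <- rbind(sim1$trials, sim2$trials)
    tr1 <- cbind(subject_id = spec$subject_id, condition = 1L,
                 sim1$q_trace)
    tr2 <- cbind(subject_id = spec$subject_id, condition = 2L,
                 sim2$q_trace)
    traces[[i]] <- rbind(tr1, tr2)
    g1$events$condition <- 1L
    g2$events$condition <- 2L
    g1$side_map$condition <- 1L
    g2$side_map$condition <- 2L
    gaze[[i]] <- rbind(g1$events, g2$events)
    sides[[i]] <- rbind(g1$side_map, g2$side_map)
  }
  structure(list(
    specs = specs,
    trials = do.call(rbind, c(trials, list(make.row.names = FALSE))),
    q_traces = do.call(rbind, c(traces, list(make.row.names = FALSE))),
    gaze_events = do.call(rbind, c(gaze, list(make.row.names = FALSE))),
    side_map = do.call(rbind, c(sides, list(make.row.names = FALSE))),
    manifest = list(seed = seed, n_subjects = n_subjects, priors = priors,
                    gaze_config = gaze_cfg)
  ), class = "synthetic_study")
}

#' Write a synthetic study to CSV files
#'
#' Emits `trials.csv`, `qvalues.csv`, `gaze_events.csv`, `side_map.csv`,
#' `ground_truth.csv` and `manifest.json` into a directory.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(study$q_traces, file.path(dir, "qvalues.csv"),
            row.names = FALSE)
  write.csv(study$gaze_events, file.path(dir, "gaze_events.csv"),
            row.names = FALSE)
  write.csv(study$side_map, file.path(dir, "side_map.csv"),
            row.names = FALSE)
  write.csv(study$specs, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
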