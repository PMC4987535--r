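#' Build the stay-regression design table
#'
#' For every trial from the second onward, records whether the subject
#' repeated the previous first-stage choice (`stay`), the previous
#' trial's reward and transition type (common = 1, rare = 0), and - in
#' the cued condition - the colour-difference regressor: the current
#' trial's colour deviation for the common state of the previously chosen
#' symbol minus the deviation for that same state for the other symbol.
#' (Because the two symbols' common states are complementary, this equals
#' the sum of the two symbols' own common-state deviations.)
#'
#' @param trials Trial table (one or more subjects), time-ordered within
#'   subject.
#' @param condition 1 or 2; condition 2 adds `colour_diff`.
#' @return `data.frame` with columns `subject_id, trial, stay,
#'   reward_prev, common_prev` (and `colour_diff` for condition 2). The
#'   first trial of each subject contributes no row.
#' @export
build_stay_design <- function(trials, condition = 1L) {
  rows <- lapply(split(trials, trials$subject_id), function(df) {
    df <- df[order(df$trial), ]
    n <- nrow(df)
    if (n < 2L) return(NULL)
    idx <- 2:n
    out <- data.frame(
      subject_id = df$subject_id[idx],
      trial = df$trial[idx],
      stay = as.integer(df$a1[idx] == df$a1[idx - 1L]),
      reward_prev = df$reward[idx - 1L],
      common_prev = as.integer(df$transition_type[idx - 1L] == "common")
    )
    if (condition == 2L) {
      # current-trial bars inform the current stay decision
      out$colour_diff <- df$colour_dev_A[idx] + df$colour_dev_B[idx]
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Stay-probability table by previous reward and transition
#'
#' Mean probability of repeating the previous first-stage choice in each
#' of the four previous-reward x previous-transition cells. Per-subject
#' cell means are computed first and then averaged across subjects, with
#' subject-clustered standard errors (sd of subject means / sqrt(n)).
#'
#' @param stay_rows Output of [build_stay_design()].
#' @return `data.frame` with one row per cell: `reward_prev, common_prev,
#'   p_stay, se, n_subjects`. Cells with no data for any subject have
#'   `p_stay = NA` (flagged missing, never coerced to zero).
#' @export
stay_probability_table <- function(stay_rows) {
  cells <- expand.grid(reward_prev = c(0L, 1L), common_prev = c(0L, 1L))
  subj_means <- aggregate(stay ~ subject_id + reward_prev + common_prev,
                          data = stay_rows, FUN = mean)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    m <- subj_means[subj_means$reward_prev == cells$reward_prev[i] &
                      subj_means$common_prev == cells$common_prev[i], ]
    if (nrow(m) == 0L) {
      data.frame(reward_prev = cells$reward_prev[i],
                 common_prev = cells$common_prev[i],
                 p_stay = NA_real_, se = NA_real_, n_subjects = 0L)
    } else {
      data.frame(reward_prev = cells$reward_prev[i],
                 common_prev = cells$common_prev[i],
                 p_stay = mean(m$stay),
                 se = if (nrow(m) > 1L) sd(m$stay) / sqrt(nrow(m)) else NA_real_,
                 n_subjects = nrow(m))
    }
  })
  do.call(rbind, out)
}

# Fit one subject's logistic regression; flags separation (perfectly
# predicted outcomes drive coefficients to +/- infinity).
fit_subject_logit <- function(df, formula) {
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  cf <- coef(fit)
  if (any(!is.finite(cf)) || any(abs(cf) > 15)) sep <- TRUE
  list(coef = cf, separated = sep, converged = fit$converged)
}

#' Stay regression with a per-subject + group-level surrogate
#'
#' Fits a logistic regression of `stay` on the design terms separately
#' for each subject by maximum likelihood, then tests each coefficient
#' across subjects with a one-sample t-test. This is a random-effects
#' surrogate for a hierarchical (mixed-effects) logistic regression: the
#' per-subject fits play the role of subject-level random coefficients
#' and the t-test that of the group-level fixed effect.
#'
#' Subjects whose fit shows complete separation are flagged and excluded
#' from the group test (with a warning); subjects with fewer than
#' `min_rows` rows are dropped.
#'
#' @param stay_rows Output of [build_stay_design()].
#' @param formula Model formula; defaults to the full factorial design
#'   for the columns present (`stay ~ reward_prev * common_prev`, with
#'   `* colour_diff` if that column exists).
#' @param min_rows Minimum rows per subject (default 10).
#' @return An object of class `group_regression`: `terms`,
#'   `subject_coefs` (matrix), `group` (`data.frame` with mean, se, t,
#'   df, p per term), `excluded` (subject ids), `n_subjects`, `n_rows`,
#'   `meta` (description of the surrogate).
#' @export
fit_stay_regression <- function(stay_rows, formula = NULL, min_rows = 10L) {
  if (is.null(formula)) {
    formula <- if ("colour_diff" %in% names(stay_rows)) {
      stay ~ reward_prev * common_prev * colour_diff
    } else {
      stay ~ reward_prev * common_prev
    }
  }
  fit_group_regression(stay_rows, formula, min_rows)
}

# Shared engine for the per-subject + t-test surrogate regressions.
fit_group_regression <- function(rows, formula, min_rows = 10L) {
  by_subj <- split(rows, rows$subject_id)
  by_subj <- Filter(function(d) nrow(d) >= min_rows, by_subj)
  if (length(by_subj) < 2L) stop("need >= 2 subjects with enough rows")
  fits <- lapply(by_subj, fit_subject_logit, formula = formula)
  terms <- names(fits[[1L]]$coef)
  coefs <- t(vapply(fits, function(f) f$coef, numeric(length(terms))))
  separated <- vapply(fits, function(f) f$separated, logical(1))
  if (any(separated)) {
    warning(sum(separated), " subject fit(s) showed separation; ",
            "excluded from the group test")
  }
  keep <- coefs[!separated, , drop = FALSE]
  group <- do.call(rbind, lapply(seq_along(terms), function(j) {
    x <- keep[, j]
    x <- x[is.finite(x)]
    if (length(x) < 2L) {
      return(data.frame(term = terms[j], mean = mean(x), se = NA_real_,
                        t = NA_real_, df = NA_integer_, p = NA_real_))
    }
    tt <- t.test(x)
    data.frame(term = terms[j], mean = mean(x),
               se = sd(x) / sqrt(length(x)),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  structure(list(
    terms = terms, subject_coefs = coefs, group = group,
    excluded = names(by_subj)[separated],
    n_subjects = sum(!separated), n_rows = nrow(rows),
    meta = paste("per-subject ML logistic fits;",
                 "group level = one-sample t-test across subjects",
                 "(random-effects surrogate for a hierarchical logit)")
  ), class = "group_regression")
}

#' @export
print.group_regression <- function(x, ...) {
  cat("Group-level regression surrogate (", x$n_subjects, " subjects, ",
      x$n_rows, " rows)\n", sep = "")
  print(x$group, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Build the first-stage choice/gaze design table
#'
#' Joins trial choices, per-trial gaze statistics and fitted Q-values
#' into the design for the first-stage choice regression: the dependent
#' variable is whether symbol B was chosen; predictors are the hybrid
#' Q-value difference (B - A), previous-trial choice of B, first and last
#' gaze on B, the last gaze's dwell time (standardized within subject),
#' and the subject's model-based weight `w` (or the median-split group
#' dummy).
#'
#' Row filters mirror the reported analyses: `"two_plus"` keeps trials
#' with two or more gazes, `"exactly_two"` keeps trials with exactly one
#' gaze on each symbol. Trials excluded by the gaze pipeline are absent
#' by construction (inner join).
#'
#' @param trials Trial table for one condition.
#' @param gaze_stats Per-trial statistics from [gaze_statistics()].
#' @param q_traj Per-subject Q-trajectories: `data.frame` with
#'   `subject_id` plus the [derive_q_trajectory()] columns.
#' @param w_table `data.frame(subject_id, w)` of fitted weights; a
#'   `group` column (`"model_based"` dummy) is derived via
#'   [classify_subjects()].
#' @param filter `"two_plus"` or `"exactly_two"`.
#' @return Design `data.frame`, one row per kept trial.
#' @export
build_choice_gaze_design <- function(trials, gaze_stats, q_traj, w_table,
                                     filter = c("two_plus", "exactly_two")) {
  filter <- match.arg(filter)
  d <- merge(trials, gaze_stats, by = c("subject_id", "trial"))
  d <- merge(d, q_traj, by = c("subject_id", "trial"))
  w_table <- w_table[, c("subject_id", "w")]
  w_table$group <- as.integer(classify_subjects(w_table$w) == "model_based")
  d <- merge(d, w_table, by = "subject_id")
  d <- d[order(d$subject_id, d$trial), ]

  prev_a1 <- ave(d$a1, d$subject_id,
                 FUN = function(a) c(NA_character_, a[-length(a)]))
  d$chose_B <- as.integer(d$a1 == "B")
  d$prev_B <- as.integer(prev_a1 == "B")
  d$q_diff <- d$qB_hybrid - d$qA_hybrid
  d$first_gaze_B <- as.integer(d$first_symbol == "B")
  d$last_gaze_B <- as.integer(d$last_symbol == "B")
  d$last_dwell <- ave(d$last_dwell_ms, d$subject_id,
                      FUN = function(x) {
                        s <- sd(x)
                        if (!is.finite(s) || s == 0) return(x * 0)
                        (x - mean(x)) / s
                      })
  keep <- if (filter == "two_plus") {
    d$n_gazes >= 2L
  } else {
    d$n_gazes == 2L & d$n_symbols_viewed == 2L
  }
  keep <- keep & !is.na(d$prev_B)
  cols <- c("subject_id", "trial", "chose_B", "q_diff", "prev_B",
            "first_gaze_B", "last_gaze_B", "last_dwell", "w", "group",
            "n_gazes")
  d[keep, cols]
}

#' Fit the first-stage choice/gaze regression surrogate
#'
#' Pooled (fixed-effects) logistic regression of the choice of symbol B
#' on the [build_choice_gaze_design()] predictors, including the
#' gaze-by-group interactions; a surrogate for the mixed-effects model of
#' the corresponding analysis. With `group_var = "w"` the continuous
#' weight replaces the group dummy.
#'
#' @param design Output of [build_choice_gaze_design()].
#' @param group_var `"group"` (median-split dummy) or `"w"` (continuous).
#' @param include_first_gaze Include the first-gaze predictor (drop for
#'   the exactly-two-gazes variant, where first and last gaze are
#'   collinear).
#' @return A fitted [glm()] object.
#' @export
fit_choice_regression <- function(design, group_var = c("group", "w"),
                                  include_first_gaze = TRUE) {
  group_var <- match.arg(group_var)
  rhs <- c("q_diff", "prev_B",
           if (include_first_gaze) "first_gaze_B",
           "last_gaze_B", "last_dwell", group_var,
           "last_dwell:last_gaze_B",
           paste0(group_var, ":last_gaze_B"),
           paste0(group_var, ":last_dwell"),
           paste0(group_var, ":last_gaze_B:last_dwell"))
  f <- stats::reformulate(rhs, response = "chose_B")
  glm(f, data = design, family = binomial())
}
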