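#' Fitting configuration
#'
#' Controls the multistart Nelder-Mead maximum-likelihood fit. The
#' reference procedure uses 10,000 random starting points; the default
#' here is scaled to 50 (configurable) with starts drawn uniformly in the
#' unconstrained (transformed) parameter space under a recorded seed.
#'
#' @param n_starts Number of random starting points (>= 1; default 50).
#' @param max_iter Maximum Nelder-Mead iterations per start.
#' @param tolerance Relative convergence tolerance passed to [optim()].
#' @param seed Integer seed for the start draws.
#' @param model One of `"cond1_hybrid"` (5 parameters),
#'   `"cond2_hybrid"` (6), `"cond1_two_rates"` (7: separate learning
#'   rates and temperatures per stage).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_starts = 50L, max_iter = 500L, tolerance = 1e-8,
                       seed = 1L,
                       model = c("cond1_hybrid", "cond2_hybrid",
                                 "cond1_two_rates")) {
  model <- match.arg(model)
  stopifnot(n_starts >= 1L)
  structure(list(n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter),
                 tolerance = tolerance, seed = as.integer(seed),
                 model = model),
            class = "fit_config")
}

# Number of free parameters per model.
model_n_params <- function(model) {
  switch(model, cond1_hybrid = 5L, cond2_hybrid = 6L, cond1_two_rates = 7L)
}

model_condition <- function(model) {
  if (model == "cond2_hybrid") 2L else 1L
}

# Stickiness search range (logit units); prevents divergence on
# perfectly sticky data.
P_STICK_MAX <- 10

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Map an unconstrained optimizer vector to the natural parameter scale.
# logit transform for rates/weights, log for beta, identity (clamped)
# for stickiness; condition-2 (w, v) use a stick-breaking map so that
# w + v <= 1 holds throughout the search.
transform_params <- function(theta, model) {
  if (model == "cond1_hybrid") {
    list(alpha1 = plogis(theta[1]), alpha2 = plogis(theta[1]),
         beta1 = exp(theta[2]), beta2 = exp(theta[2]),
         lambda = plogis(theta[3]),
         p_stick = clamp(theta[4], -P_STICK_MAX, P_STICK_MAX),
         w = plogis(theta[5]), v = 0)
  } else if (model == "cond2_hybrid") {
    w <- plogis(theta[5])
    list(alpha1 = plogis(theta[1]), alpha2 = plogis(theta[1]),
         beta1 = exp(theta[2]), beta2 = exp(theta[2]),
         lambda = plogis(theta[3]),
         p_stick = clamp(theta[4], -P_STICK_MAX, P_STICK_MAX),
         w = w, v = (1 - w) * plogis(theta[6]))
  } else {
    list(alpha1 = plogis(theta[1]), alpha2 = plogis(theta[2]),
         beta1 = exp(theta[3]), beta2 = exp(theta[4]),
         lambda = plogis(theta[5]),
         p_stick = clamp(theta[6], -P_STICK_MAX, P_STICK_MAX),
         w = plogis(theta[7]), v = 0)
  }
}

# Flatten a parameter list (or agent_params) into the 8-slot vector the
# C++ likelihood expects.
par_vector <- function(params) {
  if (inherits(params, "agent_params")) {
    c(params$alpha, params$alpha, params$beta, params$beta,
      params$lambda, params$p_stick, params$w, params$v)
  } else {
    c(params$alpha1, params$alpha2, params$beta1, params$beta2,
      params$lambda, params$p_stick, params$w, params$v)
  }
}

# Extract coded columns from a trial table once, for repeated likelihood
# evaluation.
trials_arrays <- function(trials, map = symbol_map()) {
  list(
    a1 = sym_index(trials$a1) - 1L,
    s2 = state_index(trials$s2) - 1L,
    a2 = as.integer(trials$a2),
    r = as.integer(trials$reward),
    cdA = as.numeric(trials$colour_dev_A),
    cdB = as.numeric(trials$colour_dev_B),
    commonA = state_index(map[["A"]]) - 1L
  )
}

#' Negative log-likelihood of a choice history
#'
#' Sum of `-log P(a1_t) - log P(a2_t)` over trials under the hybrid
#' learner, replaying the value updates along the observed history of
#' choices, transitions and rewards.
#'
#' @param params An [agent_params()] (or a list with two-rate fields
#'   `alpha1, alpha2, beta1, beta2, lambda, p_stick, w, v`).
#' @param trials Trial table in [generate_session()] format, time-ordered.
#' @param condition 1 or 2 (condition 2 uses the colour-deviation
#'   columns).
#' @param map A [symbol_map()].
#' @return The negative log-likelihood (non-negative).
#' @export
negative_log_likelihood <- function(params, trials, condition = 1L,
                                    map = symbol_map()) {
  arr <- trials_arrays(trials, map)
  nll <- nll_hybrid_cpp(par_vector(params), arr$a1, arr$s2, arr$a2, arr$r,
                        arr$cdA, arr$cdB, as.integer(condition),
                        arr$commonA)
  if (!is.finite(nll)) stop("non-finite likelihood: invalid parameters")
  nll
}

# Draw multistart points uniformly in transformed space. Starts are
# drawn one at a time so that, for a fixed seed, the first m starts of an
# n-start fit coincide with an m-start fit (multistart monotonicity).
draw_starts <- function(n_starts, model) {
  k <- model_n_params(model)
  beta_cols <- switch(model, cond1_hybrid = 2L, cond2_hybrid = 2L,
                      cond1_two_rates = c(3L, 4L))
  t(vapply(seq_len(n_starts), function(i) {
    u <- runif(k, -2, 2)
    u[beta_cols] <- log(0.5) +
      (u[beta_cols] + 2) / 4 * (log(20) - log(0.5))
    u
  }, numeric(k)))
}

#' Fit the hybrid model to one subject by multistart maximum likelihood
#'
#' Minimizes the negative log-likelihood with Nelder-Mead from
#' `n_starts` random starting points, with bounds enforced by smooth
#' reparameterization (logit for `alpha`, `lambda`, `w`; log for `beta`;
#' clamped identity for `p_stick`; stick-breaking for the condition-2
#' `(w, v)` simplex). Returns the best solution found.
#'
#' @param trials Trial table for one subject (>= 2 trials).
#' @param config A [fit_config()].
#' @param map A [symbol_map()].
#' @return An object of class `fit_result`: `params` (natural scale),
#'   `nll`, `bic`, `n_params`, `converged`, `best_start_index`, `model`,
#'   `n_trials`, `n_obs`, `seed`. BIC is
#'   `n_params * log(n_obs) + 2 * nll` with `n_obs = 2 * n_trials`
#'   (both stage choices enter the likelihood).
#' @export
fit_subject <- function(trials, config = fit_config(), map = symbol_map()) {
  stopifnot(nrow(trials) >= 2L)
  model <- config$model
  condition <- model_condition(model)
  arr <- trials_arrays(trials, map)
  objective <- function(theta) {
    p <- transform_params(theta, model)
    nll_hybrid_cpp(par_vector(p), arr$a1, arr$s2, arr$a2, arr$r,
                   arr$cdA, arr$cdB, condition, arr$commonA)
  }

  set.seed(config$seed)
  starts <- draw_starts(config$n_starts, model)
  best <- NULL
  best_i <- NA_integer_
  any_converged <- FALSE
  for (i in seq_len(config$n_starts)) {
    res <- tryCatch(
      optim(starts[i, ], objective, method = "Nelder-Mead",
            control = list(maxit = config$max_iter,
                           reltol = config$tolerance)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (res$convergence == 0L) any_converged <- TRUE
    if (is.null(best) || res$value < best$value) {
      best <- res
      best_i <- i
    }
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, nll = NA_real_, bic = NA_real_,
                          n_params = model_n_params(model),
                          converged = FALSE, best_start_index = NA_integer_,
                          model = model, n_trials = nrow(trials),
                          n_obs = 2L * nrow(trials), seed = config$seed),
                     class = "fit_result"))
  }
  pars <- transform_params(best$par, model)
  n_obs <- 2L * nrow(trials)
  k <- model_n_params(model)
  structure(list(
    params = pars, nll = best$value,
    bic = k * log(n_obs) + 2 * best$value,
    n_params = k, converged = any_converged, best_start_index = best_i,
    model = model, n_trials = nrow(trials), n_obs = n_obs,
    seed = config$seed
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Hybrid-model fit (", x$model, ")\n", sep = "")
  if (is.null(x$params)) {
    cat("  no start converged\n")
    return(invisible(x))
  }
  est <- unlist(x$params)
  cat("  ", paste(sprintf("%s=%.3f", names(est), est), collapse = " "), "\n")
  cat(sprintf("  nll=%.3f  BIC=%.3f  (%d params, %d obs, start %d)\n",
              x$nll, x$bic, x$n_params, x$n_obs, x$best_start_index))
  invisible(x)
}

#' Compare fitted models by BIC
#'
#' Given several [fit_subject()] results for the *same* data, returns the
#' name of the model with the lowest BIC (ties and equal parameter counts
#' resolve by the likelihood).
#'
#' @param results Named list of `fit_result` objects.
#' @return Name of the preferred model (attribute `bic` carries the BIC
#'   table).
#' @export
compare_models <- function(results) {
  stopifnot(length(results) >= 2L, !is.null(names(results)))
  n_obs <- vapply(results, function(r) r$n_obs, integer(1))
  if (length(unique(n_obs)) != 1L) {
    stop("models were fit to different numbers of observations")
  }
  bic <- vapply(results, function(r) r$bic, numeric(1))
  nll <- vapply(results, function(r) r$nll, numeric(1))
  ord <- order(bic, nll)
  preferred <- names(results)[ord[1L]]
  attr(preferred, "bic") <- bic
  preferred
}

#' Derive trial-by-trial Q-values from fitted parameters
#'
#' Replays a subject's observed history under the given parameters and
#' records, for every trial, the pre-choice model-free, model-based and
#' hybrid values of both first-stage symbols. Matches the Q-trace emitted
#' by [simulate_agent()] when replaying the generating parameters on the
#' generated history.
#'
#' @param params An [agent_params()].
#' @param trials Trial table, time-ordered.
#' @param condition 1 or 2.
#' @param map A [symbol_map()].
#' @return `data.frame` with columns `trial, qA_mf, qB_mf, qA_mb, qB_mb,
#'   qA_hybrid, qB_hybrid`.
#' @export
derive_q_trajectory <- function(params, trials, condition = 1L,
                                map = symbol_map()) {
  st <- learner_state()
  n <- nrow(trials)
  out <- data.frame(trial = trials$trial,
                    qA_mf = numeric(n), qB_mf = numeric(n),
                    qA_mb = numeric(n), qB_mb = numeric(n),
                    qA_hybrid = numeric(n), qB_hybrid = numeric(n))
  for (t in seq_len(n)) {
    cd <- if (condition == 2L) {
      c(A = trials$colour_dev_A[t], B = trials$colour_dev_B[t])
    } else NULL
    out$qA_mf[t] <- st$q1_mf[["A"]]
    out$qB_mf[t] <- st$q1_mf[["B"]]
    out$qA_mb[t] <- model_based_q(st, "A")
    out$qB_mb[t] <- model_based_q(st, "B")
    out$qA_hybrid[t] <- hybrid_q(st, "A", params, condition, cd, map)
    out$qB_hybrid[t] <- hybrid_q(st, "B", params, condition, cd, map)
    a1 <- trials$a1[t]
    s2 <- trials$s2[t]
    a2 <- trials$a2[t]
    r <- trials$reward[t]
    st <- update_stage1_mf(st, a1, s2, a2, r, params)
    st <- update_stage2(st, s2, a2, r, params)
    st$n_trans[a1, s2] <- st$n_trans[a1, s2] + 1L
    st$prev_a1 <- a1
  }
  out
}

#' Median-split classification of subjects by model-based weight
#'
#' Subjects whose fitted `w` lies below the sample median are labelled
#' `"model_free"`, the rest (including ties at the median)
#' `"model_based"`. If all weights are equal the split is degenerate:
#' everybody is labelled model-based and a warning is emitted.
#'
#' @param w_values Numeric vector of per-subject model-based weights
#'   (length >= 2).
#' @return Character vector of labels; attributes `median` and
#'   `tie_policy` record the split.
#' @export
classify_subjects <- function(w_values) {
  stopifnot(length(w_values) >= 2L)
  med <- median(w_values)
  if (length(unique(w_values)) == 1L) {
    warning("all weights equal: degenerate median split, ",
            "all subjects labelled model_based")
  }
  labels <- ifelse(w_values < med, "model_free", "model_based")
  attr(labels, "median") <- med
  attr(labels, "tie_policy") <- ">= median is model_based"
  labels
}
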