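# Independent replay oracle for the hybrid-model likelihood.
#
# Deliberately written from the model definition, without reusing any
# package code: naive softmax (no log-sum-exp), named vectors, explicit
# per-trial recomputation. Used to cross-check the package's likelihood
# on small instances.
oracle_nll <- function(pars, trials, condition = 1, map_A_common = "blue") {
  states <- c("blue", "purple")
  q2 <- matrix(0, 2, 2, dimnames = list(states, NULL))
  q1 <- c(A = 0, B = 0)
  nb <- c(A = 0, B = 0) # times blue reached per symbol
  np <- c(A = 0, B = 0) # times purple reached per symbol
  common <- c(A = map_A_common, B = setdiff(states, map_A_common))
  prev <- NULL
  ll <- 0
  for (t in seq_len(nrow(trials))) {
    row <- trials[t, ]
    qh <- vapply(c("A", "B"), function(a) {
      pb <- (nb[[a]] + 1) / (nb[[a]] + np[[a]] + 2)
      qmb <- pb * max(q2["blue", ]) + (1 - pb) * max(q2["purple", ])
      if (condition == 1) {
        pars$w * qmb + (1 - pars$w) * q1[[a]]
      } else {
        cd <- if (a == "A") row$colour_dev_A else row$colour_dev_B
        oth <- setdiff(states, common[[a]])
        dq <- cd * (max(q2[common[[a]], ]) - max(q2[oth, ]))
        pars$w * qmb + pars$v * dq + (1 - pars$w - pars$v) * q1[[a]]
      }
    }, numeric(1))
    stick <- c(A = 0, B = 0)
    if (!is.null(prev)) stick[[prev]] <- pars$p_stick
    z1 <- pars$beta * qh + stick
    p1 <- exp(z1) / sum(exp(z1))
    ll <- ll + log(p1[[row$a1]])
    z2 <- pars$beta * q2[row$s2, ]
    p2 <- exp(z2) / sum(exp(z2))
    ll <- ll + log(p2[[row$a2 + 1]])

    q2sa <- q2[row$s2, row$a2 + 1]
    q1[[row$a1]] <- q1[[row$a1]] + pars$alpha * (q2sa - q1[[row$a1]]) +
      pars$alpha * pars$lambda * (row$reward - q2sa)
    q2[row$s2, row$a2 + 1] <- q2sa + pars$alpha * (row$reward - q2sa)
    if (row$s2 == "blue") nb[[row$a1]] <- nb[[row$a1]] + 1
    else np[[row$a1]] <- np[[row$a1]] + 1
    prev <- row$a1
  }
  -ll
}
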