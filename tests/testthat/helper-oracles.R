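# Independent oracles used by the test suite. Each is deliberately built on a
# different representation than the implementation it checks: numerical
# integration instead of log-Beta algebra, raw reward histories instead of the
# count lattice, and truncated-lattice value iteration instead of the
# finite-horizon retirement DP.

# marginal-likelihood oracle by adaptive numerical integration over the
# reward-probability parameter(s)
oracle_coupling_posterior <- function(counts, priors) {
  lik <- function(p, s, f_, a, b) p^s * (1 - p)^f_ * stats::dbeta(p, a, b)
  ml_coupled <- stats::integrate(function(p)
    lik(p, counts[["s1"]] + counts[["f2"]], counts[["f1"]] + counts[["s2"]],
        priors$a0, priors$b0), 0, 1, rel.tol = 1e-12)$value
  ml_indep <- stats::integrate(function(p)
    lik(p, counts[["s1"]], counts[["f1"]], priors$a1, priors$b1),
    0, 1, rel.tol = 1e-12)$value *
    stats::integrate(function(p)
      lik(p, counts[["s2"]], counts[["f2"]], priors$a2, priors$b2),
      0, 1, rel.tol = 1e-12)$value
  k <- priors$kappa0
  k * ml_coupled / (k * ml_coupled + (1 - k) * ml_indep)
}

oracle_predictive_reward <- function(counts, priors, action) {
  pc <- oracle_coupling_posterior(counts, priors)
  # posterior-mean rewards per structure by one more integration step
  mom <- function(s, f_, a, b) {
    num <- stats::integrate(function(p) p^(s + 1) * (1 - p)^f_ *
                              stats::dbeta(p, a, b), 0, 1,
                            rel.tol = 1e-12)$value
    den <- stats::integrate(function(p) p^s * (1 - p)^f_ *
                              stats::dbeta(p, a, b), 0, 1,
                            rel.tol = 1e-12)$value
    num / den
  }
  if (action == 1) {
    m_c <- mom(counts[["s1"]] + counts[["f2"]], counts[["f1"]] + counts[["s2"]],
               priors$a0, priors$b0)
    m_i <- mom(counts[["s1"]], counts[["f1"]], priors$a1, priors$b1)
  } else {
    m_c <- 1 - mom(counts[["s1"]] + counts[["f2"]],
                   counts[["f1"]] + counts[["s2"]], priors$a0, priors$b0)
    m_i <- mom(counts[["s2"]], counts[["f2"]], priors$a2, priors$b2)
  }
  pc * m_c + (1 - pc) * m_i
}

# exhaustive backward induction over raw reward histories (no count-state
# merging): action values at the root for a finite horizon
oracle_tree_values <- function(counts, priors, gamma, horizon) {
  qval <- function(ct, a, depth) {
    p <- predictive_reward(arm_counts(ct[1], ct[2], ct[3], ct[4]), priors, a)
    if (depth == 1) return(p)
    succ <- ct; fail <- ct
    if (a == 1) { succ[1] <- succ[1] + 1; fail[2] <- fail[2] + 1 }
    else { succ[3] <- succ[3] + 1; fail[4] <- fail[4] + 1 }
    p * (1 + gamma * max(qval(succ, 1, depth - 1), qval(succ, 2, depth - 1))) +
      (1 - p) * gamma * max(qval(fail, 1, depth - 1),
                            qval(fail, 2, depth - 1))
  }
  ct <- as.integer(counts)
  c(qval(ct, 1, horizon), qval(ct, 2, horizon))
}

# Gittins oracle: bisection where each evaluation is dense value iteration on
# the truncated (a, b) lattice with an always-available retirement option worth
# lambda / (1 - gamma) (and the same value at the truncation boundary)
oracle_gittins <- function(a, b, gamma, depth = 250, tol = 1e-5) {
  margin <- function(lambda) {
    retire <- lambda / (1 - gamma)
    v_next <- rep(retire, depth + 1)
    root_cont <- NA_real_
    for (n in (depth - 1):0) {
      i <- 0:n
      p <- (a + i) / (a + b + n)
      cont <- p * (1 + gamma * v_next[i + 2]) + (1 - p) * gamma * v_next[i + 1]
      v_next <- pmax(retire, cont)
      if (n == 0) root_cont <- cont
    }
    root_cont - retire
  }
  lo <- a / (a + b); hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (margin(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# shared tie-break used when comparing policies state-wise in tests
decide_action <- function(v1, v2, pulls1, pulls2, tol = 1e-12) {
  ifelse(abs(v1 - v2) <= tol, ifelse(pulls2 < pulls1, 2L, 1L),
         ifelse(v2 > v1, 2L, 1L))
}

# small scored-log builder for pure-logic tests of the report functions
make_scored_stub <- function(pred_a, pred_b, action,
                             models = c("structure", "independent")) {
  n <- length(action)
  df <- data.frame(environment = rep("independent", n), action = action,
                   better = rep(1L, n), diagnostic = pred_a != pred_b,
                   exploration = rep("none", n),
                   task_learning = rep(FALSE, n))
  preds <- list(pred_a, pred_b, pred_a, pred_b)
  for (k in seq_along(c("structure", "independent", "coupled",
                        "qlearning"))) {
    m <- c("structure", "independent", "coupled", "qlearning")[k]
    df[[paste0("pred_", m)]] <- preds[[k]]
    df[[paste0("tie_", m)]] <- FALSE
    df[[paste0("correct_", m)]] <- as.numeric(preds[[k]] == action)
  }
  df
}
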