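#' Q-learning parameters
#'
#' The five free parameters of the model-free baseline: initial action values,
#' learning rate, soft-max inverse temperature and discount.
#'
#' @param q1_init,q2_init Initial action values.
#' @param alpha Learning rate in `[0, 1]`; 0 ignores all rewards, 1 keeps only
#'   the last.
#' @param beta Soft-max inverse temperature; 0 chooses uniformly at random,
#'   large positive values always take the higher-valued option, negative
#'   values invert the preference.
#' @param gamma_q Discount factor in `[0, 1]` inside the temporal-difference
#'   target.
#' @return An object of class `q_params`.
#' @export
q_params <- function(q1_init = 0.5, q2_init = 0.5, alpha = 0.1, beta = 5,
                     gamma_q = 0) {
  if (is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)
  if (is.na(gamma_q) || gamma_q < 0 || gamma_q > 1)
    stop("gamma_q must lie in [0, 1]", call. = FALSE)
  stopifnot(is.finite(q1_init), is.finite(q2_init), is.finite(beta))
  structure(list(q1_init = q1_init, q2_init = q2_init, alpha = alpha,
                 beta = beta, gamma_q = gamma_q),
            class = "q_params")
}

#' @export
print.q_params <- function(x, ...) {
  cat(sprintf("<q_params> q_init (%g, %g), alpha %g, beta %g, gamma_q %g\n",
              x$q1_init, x$q2_init, x$alpha, x$beta, x$gamma_q))
  invisible(x)
}

#' Soft-max probability of choosing option 1
#'
#' `exp(beta q1) / (exp(beta q1) + exp(beta q2))`, computed with
#' max-subtraction so extreme temperatures do not overflow.
#'
#' @param state Numeric vector `c(q1, q2)` of current action values.
#' @param beta Inverse temperature.
#' @return Probability of option 1.
#' @examples
#' softmax_prob(c(1, 0), 1) # 1 / (1 + exp(-1))
#' @export
softmax_prob <- function(state, beta) {
  stopifnot(length(state) == 2, all(is.finite(state)), is.finite(beta))
  z <- beta * state
  z <- z - max(z)
  exp(z[1]) / sum(exp(z))
}

#' Temporal-difference update of the action values
#'
#' `Q_a <- Q_a + alpha (reward + gamma_q max(q1, q2) - Q_a)` for the chosen
#' option; the other value is untouched. Rewards are scored on the 0/1 scale.
#'
#' @param state Numeric vector `c(q1, q2)`.
#' @param action Chosen option, 1 or 2.
#' @param reward Observed reward, 0 or 1.
#' @param params A [q_params()].
#' @return The updated `c(q1, q2)`.
#' @export
td_update <- function(state, action, reward, params) {
  stopifnot(length(state) == 2, action %in% c(1, 2), reward %in% c(0, 1))
  target <- reward + params$gamma_q * max(state)
  state[action] <- state[action] + params$alpha * (target - state[action])
  state
}

#' Default search grid for Q-learning fitting
#'
#' Initial values on a coarse unit grid, learning rates across `(0, 1)`, a
#' temperature grid spanning negative through strongly positive values with
#' log-spaced magnitudes, and a handful of discounts.
#'
#' @return A list of candidate values per parameter.
#' @export
q_fit_grid <- function() {
  list(q_init = c(0, 0.25, 0.5, 0.75, 1),
       alpha = seq(0.05, 0.95, by = 0.1),
       beta = c(-5, -2, -1, -0.5, 0, 0.5, 1, 2, 5, 10, 15, 20),
       gamma_q = c(0, 0.3, 0.6, 0.9, 0.98))
}

# prediction rate of one parameter set on a trial log (modal action, ties 0.5)
.q_rate <- function(action, reward, task_id, p) {
  cpp_q_rates(as.integer(action), as.numeric(reward), as.integer(task_id),
              matrix(c(p$q1_init, p$q2_init, p$alpha, p$beta, p$gamma_q), 1))[1]
}

#' Prediction rate of a Q-learning parameter set on a trial log
#'
#' The fraction of trials whose recorded action is the modal action of the
#' soft-max (value ties score 0.5). The Q state resets to the initial values
#' at every task boundary.
#'
#' @param log A trial log (data.frame with columns `block`, `task`, `action`,
#'   `reward`, ordered by trial within task).
#' @param params A [q_params()].
#' @return The prediction rate in `[0, 1]`.
#' @export
q_prediction_rate <- function(log, params) {
  stopifnot(nrow(log) >= 1)
  task_id <- as.integer(factor(paste(log$block, log$task)))
  .q_rate(log$action, log$reward, task_id, params)
}

#' Fit Q-learning to a trial log by prediction-rate maximization
#'
#' Coarse grid search over the five parameters followed by rounds of
#' coordinate descent around the best grid point. Deterministic given the
#' grid; the returned rate is never below the best grid point's rate.
#'
#' @param log A trial log for a single agent (columns `block`, `task`,
#'   `action`, `reward`, in trial order).
#' @param grid Candidate values per parameter, as from [q_fit_grid()].
#' @param refine_rounds Rounds of coordinate descent after the grid search.
#' @return A list with elements `params` (a [q_params()]) and `rate`.
#' @export
fit_qlearning <- function(log, grid = q_fit_grid(), refine_rounds = 3) {
  if (is.null(log) || nrow(log) < 1)
    stop("trial log must contain at least one trial", call. = FALSE)
  task_id <- as.integer(factor(paste(log$block, log$task)))
  action <- as.integer(log$action); reward <- as.numeric(log$reward)
  combos <- as.matrix(expand.grid(q1 = grid$q_init, q2 = grid$q_init,
                                  alpha = grid$alpha, beta = grid$beta,
                                  gq = grid$gamma_q))
  rates <- cpp_q_rates(action, reward, task_id, combos)
  best <- combos[which.max(rates), ]
  best_rate <- max(rates)

  eval1 <- function(p) cpp_q_rates(action, reward, task_id, matrix(p, 1))[1]
  clamp01 <- function(x) pmin(1, pmax(0, x))
  for (round in seq_len(refine_rounds)) {
    step <- 0.5^round
    for (k in seq_along(best)) {
      cand <- best[k] + step * c(-0.5, -0.25, -0.1, 0, 0.1, 0.25, 0.5) *
        (if (k == 4) 10 else 1)  # beta lives on a wider scale
      if (k %in% c(3, 5)) cand <- clamp01(cand)
      for (v in unique(cand)) {
        p <- best; p[k] <- v
        r <- eval1(p)
        if (r > best_rate) { best_rate <- r; best <- p }
      }
    }
  }
  list(params = q_params(best[[1]], best[[2]], best[[3]], best[[4]],
                         best[[5]]),
       rate = best_rate)
}
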