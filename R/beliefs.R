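#' Success/failure counts for a two-armed bandit task
#'
#' Sufficient statistics of the reward history within one task: the number of
#' successes and failures observed on each option. Together with the priors
#' these counts fully determine every belief quantity used by the policies.
#'
#' @param s1,f1 Successes and failures observed on option 1.
#' @param s2,f2 Successes and failures observed on option 2.
#' @return An object of class `arm_counts`: a named integer vector with
#'   elements `s1`, `f1`, `s2`, `f2`.
#' @examples
#' arm_counts(2, 1, 0, 3)
#' @export
arm_counts <- function(s1 = 0L, f1 = 0L, s2 = 0L, f2 = 0L) {
  x <- c(s1 = s1, f1 = f1, s2 = s2, f2 = f2)
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    stop("arm counts must be non-negative integers", call. = FALSE)
  }
  structure(as.integer(round(x)), names = c("s1", "f1", "s2", "f2"),
            class = "arm_counts")
}

#' @export
print.arm_counts <- function(x, ...) {
  cat(sprintf("<arm_counts> option 1: %d/%d  option 2: %d/%d  (N = %d)\n",
              x[["s1"]], x[["s1"]] + x[["f1"]], x[["s2"]],
              x[["s2"]] + x[["f2"]], sum(x)))
  invisible(x)
}

#' Prior hyperparameters for the structure-learning belief
#'
#' Beta hyperparameters for each option's reward probability under the
#' independent reward model (`a1,b1` and `a2,b2`), Beta hyperparameters for the
#' single shared reward probability under the coupled model (`a0,b0`), and the
#' prior probability `kappa0` that the environment is coupled. The defaults are
#' uniform `Beta(1,1)` priors everywhere and an agnostic `kappa0 = 0.5`.
#'
#' @param a1,b1 Beta prior for option 1 (independent model).
#' @param a2,b2 Beta prior for option 2 (independent model).
#' @param a0,b0 Beta prior for the shared parameter (coupled model).
#' @param kappa0 Prior probability of a coupled environment, in `[0, 1]`.
#' @return An object of class `bandit_priors`.
#' @examples
#' bandit_priors()                 # uniform, agnostic about coupling
#' bandit_priors(kappa0 = 1)      # certain the environment is coupled
#' @export
bandit_priors <- function(a1 = 1, b1 = 1, a2 = 1, b2 = 1, a0 = 1, b0 = 1,
                          kappa0 = 0.5) {
  hp <- c(a1 = a1, b1 = b1, a2 = a2, b2 = b2, a0 = a0, b0 = b0)
  if (anyNA(hp) || any(hp <= 0)) {
    stop("Beta hyperparameters must be strictly positive", call. = FALSE)
  }
  if (is.na(kappa0) || kappa0 < 0 || kappa0 > 1) {
    stop("kappa0 must lie in [0, 1]", call. = FALSE)
  }
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, a0 = a0, b0 = b0,
                 kappa0 = kappa0),
            class = "bandit_priors")
}

#' @export
print.bandit_priors <- function(x, ...) {
  cat(sprintf(paste0("<bandit_priors> independent: Beta(%g,%g), Beta(%g,%g); ",
                     "coupled: Beta(%g,%g); P(coupled) = %g\n"),
              x$a1, x$b1, x$a2, x$b2, x$a0, x$b0, x$kappa0))
  invisible(x)
}

#' Belief state: counts plus priors
#'
#' The pair (counts, priors) is a sufficient belief state: the coupling
#' posterior, the predictive reward probabilities and all policy values are
#' recoverable from it alone.
#'
#' @param counts An [arm_counts()] object.
#' @param priors A [bandit_priors()] object.
#' @return An object of class `belief_state` with elements `counts`, `priors`.
#' @export
belief_state <- function(counts = arm_counts(), priors = bandit_priors()) {
  stopifnot(inherits(counts, "arm_counts"), inherits(priors, "bandit_priors"))
  structure(list(counts = counts, priors = priors), class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  print(x$counts)
  print(x$priors)
  cat(sprintf("  P(coupled | counts) = %.4f\n",
              coupling_posterior(x$counts, x$priors)))
  invisible(x)
}

#' Record one observed reward
#'
#' Increments the success or failure count of the chosen option; the Bayesian
#' belief update is exactly this increment thanks to conjugacy.
#'
#' @param counts An [arm_counts()] object.
#' @param action Chosen option, 1 or 2.
#' @param reward Observed binary reward, 0 or 1.
#' @return The updated `arm_counts`.
#' @examples
#' update_counts(arm_counts(), action = 1, reward = 1)
#' @export
update_counts <- function(counts, action, reward) {
  stopifnot(inherits(counts, "arm_counts"))
  if (length(action) != 1 || !action %in% c(1, 2)) {
    stop("action must be 1 or 2", call. = FALSE)
  }
  if (length(reward) != 1 || !reward %in% c(0, 1)) {
    stop("reward must be 0 or 1", call. = FALSE)
  }
  i <- if (action == 1) (if (reward == 1) 1L else 2L) else
    (if (reward == 1) 3L else 4L)
  counts[i] <- counts[i] + 1L
  counts
}

#' Posterior probability that the environment is coupled
#'
#' Compares the marginal likelihood of the observed counts under the coupled
#' model (one shared Beta-distributed reward probability; a success on option 1
#' and a failure on option 2 both count toward the shared parameter, while a
#' failure on option 1 and a success on option 2 count toward its complement)
#' against the independent model (separate Beta parameters per option), and
#' combines the resulting Bayes factor with the prior odds of coupling.
#'
#' All Beta-function ratios are evaluated as log-gamma differences and the
#' posterior odds are assembled in log space before the logistic map, so counts
#' of several hundred do not overflow. Degenerate priors (`kappa0` exactly 0 or
#' 1) short-circuit to that value without evaluating likelihoods.
#'
#' @param counts An [arm_counts()] object.
#' @param priors A [bandit_priors()] object; its `kappa0` is the prior
#'   probability of coupling (possibly carried over from a previous task).
#' @return `P(coupled | counts)`, a probability.
#' @examples
#' coupling_posterior(arm_counts(10, 0, 0, 10), bandit_priors()) # near 1
#' coupling_posterior(arm_counts(10, 0, 10, 0), bandit_priors()) # near 0
#' @export
coupling_posterior <- function(counts, priors) {
  stopifnot(inherits(counts, "arm_counts"), inherits(priors, "bandit_priors"))
  k <- priors$kappa0
  if (k == 0 || k == 1) return(k)
  s1 <- counts[["s1"]]; f1 <- counts[["f1"]]
  s2 <- counts[["s2"]]; f2 <- counts[["f2"]]
  log_odds <- log(k) - log1p(-k) +
    lbeta(priors$a0 + s1 + f2, priors$b0 + f1 + s2) - lbeta(priors$a0, priors$b0) -
    (lbeta(priors$a1 + s1, priors$b1 + f1) - lbeta(priors$a1, priors$b1)) -
    (lbeta(priors$a2 + s2, priors$b2 + f2) - lbeta(priors$a2, priors$b2))
  stats::plogis(log_odds)
}

#' Predictive probability of reward for an option
#'
#' Mixture of the coupled and independent posterior-mean predictions, weighted
#' by the coupling posterior. Under the coupled model the prediction for
#' option 1 pools option-1 successes with option-2 failures; under the
#' independent model each option uses only its own counts.
#'
#' @inheritParams coupling_posterior
#' @param action Option, 1 or 2.
#' @return The predictive reward probability, in (0, 1).
#' @examples
#' predictive_reward(arm_counts(), bandit_priors(), 1) # 0.5 by symmetry
#' @export
predictive_reward <- function(counts, priors, action) {
  stopifnot(inherits(counts, "arm_counts"), inherits(priors, "bandit_priors"))
  if (!action %in% c(1, 2)) stop("action must be 1 or 2", call. = FALSE)
  pc <- coupling_posterior(counts, priors)
  s1 <- counts[["s1"]]; f1 <- counts[["f1"]]
  s2 <- counts[["s2"]]; f2 <- counts[["f2"]]
  n <- s1 + f1 + s2 + f2
  if (action == 1) {
    m_c <- (priors$a0 + s1 + f2) / (priors$a0 + priors$b0 + n)
    m_i <- (priors$a1 + s1) / (priors$a1 + priors$b1 + s1 + f1)
  } else {
    m_c <- (priors$b0 + f1 + s2) / (priors$a0 + priors$b0 + n)
    m_i <- (priors$a2 + s2) / (priors$a2 + priors$b2 + s2 + f2)
  }
  pc * m_c + (1 - pc) * m_i
}
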