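#' Solver settings for the dynamic-programming policies
#'
#' @param gamma Discount factor in `[0, 1)`; equivalently the per-trial
#'   continuation probability of the geometrically stopped task. Default 0.98.
#' @param horizon Lookahead depth of the belief-state DP for the
#'   structure-learning policy. Truncation changes any value by at most
#'   `gamma^horizon / (1 - gamma)` reward units. Default 150.
#' @param index_tolerance Bisection tolerance for the Gittins calibration
#'   reward. Default 1e-4.
#' @param gittins_horizon DP depth used inside each Gittins bisection step;
#'   at `gamma = 0.98` the default 500 leaves a tail weight of
#'   `0.98^500` (about 4e-5).
#' @param max_states Capacity budget: the largest admissible single lattice
#'   level; a horizon needing more signals a capacity error.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(gamma = 0.98, horizon = 150, index_tolerance = 1e-4,
                          gittins_horizon = 500, max_states = 5e7) {
  if (is.na(gamma) || gamma < 0 || gamma >= 1)
    stop("gamma must lie in [0, 1)", call. = FALSE)
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  if (index_tolerance <= 0) stop("index_tolerance must be > 0", call. = FALSE)
  structure(list(gamma = gamma, horizon = as.integer(horizon),
                 index_tolerance = index_tolerance,
                 gittins_horizon = as.integer(gittins_horizon),
                 max_states = max_states),
            class = "solver_config")
}

# value-tie tolerance used by every policy
.TIE_TOL <- 1e-12

# Deterministic tie-break: the option with fewer pulls (it carries more
# information), then option 1.
.decide <- function(values, counts, model_id) {
  tie <- abs(values[1] - values[2]) <= .TIE_TOL
  if (tie) {
    pulls <- c(counts[["s1"]] + counts[["f1"]], counts[["s2"]] + counts[["f2"]])
    action <- if (pulls[2] < pulls[1]) 2L else 1L
  } else {
    action <- if (values[2] > values[1]) 2L else 1L
  }
  structure(list(values = unname(values), action = action, tie = tie,
                 model_id = model_id),
            class = "policy_decision")
}

#' @export
print.policy_decision <- function(x, ...) {
  cat(sprintf("<policy_decision> %s: values (%.5f, %.5f) -> option %d%s\n",
              x$model_id, x$values[1], x$values[2], x$action,
              if (x$tie) " (tie)" else ""))
  invisible(x)
}

.gittins_cache <- new.env(parent = emptyenv())

#' Gittins index of a Beta-Bernoulli arm
#'
#' The calibration reward `lambda` at which retiring to a deterministic option
#' paying `lambda` each step and continuing to play the Bernoulli arm with a
#' `Beta(a, b)` belief are equally valuable. Found by bisection on `lambda`,
#' each evaluation a finite-horizon DP over the arm's own (success, failure)
#' lattice with a retirement option worth
#' `lambda * (1 - gamma^remaining) / (1 - gamma)`.
#'
#' At `gamma = 0` the index equals the posterior mean `a / (a + b)`; for
#' `gamma > 0` it exceeds it — the excess is the value of what can still be
#' learned by pulling the arm.
#'
#' @param a,b Positive pseudo-counts (prior plus observed successes/failures);
#'   vectors are recycled to common length.
#' @param config A [solver_config()].
#' @return Numeric vector of index values in `[0, 1]`.
#' @examples
#' gittins_index(1, 1, solver_config(gamma = 0))    # 0.5
#' gittins_index(1, 1, solver_config(gamma = 0.9, gittins_horizon = 200))
#' @export
gittins_index <- function(a, b, config = solver_config()) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (anyNA(a) || anyNA(b) || any(a <= 0) || any(b <= 0))
    stop("pseudo-counts must be positive", call. = FALSE)
  keys <- sprintf("%.17g|%.17g|%.17g|%d|%g", a, b, config$gamma,
                  config$gittins_horizon, config$index_tolerance)
  out <- numeric(n)
  hit <- vapply(keys, exists, logical(1), envir = .gittins_cache,
                inherits = FALSE)
  if (any(hit)) {
    out[hit] <- vapply(keys[hit], get, numeric(1), envir = .gittins_cache,
                       inherits = FALSE)
  }
  if (any(!hit)) {
    miss <- which(!hit)
    u <- !duplicated(keys[miss])
    idx <- miss[u]
    vals <- cpp_gittins(a[idx], b[idx], config$gamma, config$gittins_horizon,
                        config$index_tolerance)
    for (i in seq_along(idx)) assign(keys[idx[i]], vals[i],
                                     envir = .gittins_cache)
    out[miss] <- vals[match(keys[miss], keys[idx])]
  }
  out
}

#' Tabulate Gittins indices over a grid of pseudo-counts
#'
#' @param max_total Largest total pseudo-count `a + b` tabulated; the grid is
#'   `a = a0 + 0:k`, `b = b0 + 0:k` with `a + b <= a0 + b0 + max_total`.
#' @param config A [solver_config()].
#' @param a0,b0 Prior hyperparameters anchoring the grid.
#' @return A data.frame with columns `a`, `b`, `index`.
#' @export
gittins_table <- function(max_total = 50, config = solver_config(),
                          a0 = 1, b0 = 1) {
  grid <- expand.grid(s = 0:max_total, f = 0:max_total)
  grid <- grid[grid$s + grid$f <= max_total, ]
  data.frame(a = a0 + grid$s, b = b0 + grid$f,
             index = gittins_index(a0 + grid$s, b0 + grid$f, config))
}

#' Fixed-independent-structure policy (Gittins)
#'
#' Scores each option by the Gittins index of its own Beta posterior and picks
#' the larger; optimal for independent discounted Bernoulli arms.
#'
#' @param belief A [belief_state()].
#' @param config A [solver_config()].
#' @return A `policy_decision` with per-option index values.
#' @export
independent_policy <- function(belief, config = solver_config()) {
  stopifnot(inherits(belief, "belief_state"))
  ct <- belief$counts; pr <- belief$priors
  v <- gittins_index(c(pr$a1 + ct[["s1"]], pr$a2 + ct[["s2"]]),
                     c(pr$b1 + ct[["f1"]], pr$b2 + ct[["f2"]]), config)
  .decide(v, ct, "independent")
}

#' Expected reward of an option under the fixed coupled model
#'
#' Posterior mean of the shared reward parameter: successes of option 1 and
#' failures of option 2 count toward option 1; the rest toward option 2.
#'
#' @inheritParams coupling_posterior
#' @param action Option, 1 or 2.
#' @return Posterior-mean reward probability.
#' @examples
#' coupled_value(arm_counts(2, 1, 0, 3), bandit_priors(), 1) # 0.75
#' @export
coupled_value <- function(counts, priors, action) {
  stopifnot(inherits(counts, "arm_counts"), inherits(priors, "bandit_priors"))
  if (!action %in% c(1, 2)) stop("action must be 1 or 2", call. = FALSE)
  n <- sum(counts)
  if (action == 1) {
    (priors$a0 + counts[["s1"]] + counts[["f2"]]) / (priors$a0 + priors$b0 + n)
  } else {
    (priors$b0 + counts[["f1"]] + counts[["s2"]]) / (priors$a0 + priors$b0 + n)
  }
}

#' Fixed-coupled-structure policy (myopic)
#'
#' Under known coupling, every pull is equally informative about both options,
#' so exploration carries no extra value and the greedy choice is optimal: pick
#' the option with the greater pooled evidence.
#'
#' @inheritParams independent_policy
#' @return A `policy_decision`.
#' @export
coupled_policy <- function(belief) {
  stopifnot(inherits(belief, "belief_state"))
  v <- c(coupled_value(belief$counts, belief$priors, 1),
         coupled_value(belief$counts, belief$priors, 2))
  .decide(v, belief$counts, "coupled")
}

#' Action values of the structure-learning policy
#'
#' Solves the Bellman equations over the count lattice
#' `V(c) = max_a P_a(c) (1 + gamma V(c + succ_a)) + (1 - P_a(c)) gamma V(c + fail_a)`
#' where `P_a` is the structure-mixture predictive reward (which embeds the
#' coupling posterior at every future node), by backward induction to depth
#' `config$horizon` with terminal value 0. Because counts — not reward
#' orderings — index states, a depth-`H` lookahead costs `choose(H + 4, 4)`
#' evaluations instead of `4^H`.
#'
#' @inheritParams independent_policy
#' @return Named numeric vector `c(q1, q2)` of discounted action values.
#' @export
structure_value <- function(belief, config = solver_config()) {
  stopifnot(inherits(belief, "belief_state"))
  ct <- belief$counts; pr <- belief$priors
  q <- cpp_struct_q_batch(matrix(as.integer(ct), 1), pr$kappa0,
                          pr$a1, pr$b1, pr$a2, pr$b2, pr$a0, pr$b0,
                          config$gamma, config$horizon, config$max_states)
  c(q1 = q[1, 1], q2 = q[1, 2])
}

#' Structure-learning policy
#'
#' Optimal action under joint uncertainty about the reward probabilities and
#' about whether the environment is coupled; wraps [structure_value()] with the
#' deterministic tie-break rule.
#'
#' @inheritParams independent_policy
#' @return A `policy_decision` with `model_id = "structure"`.
#' @export
structure_policy <- function(belief, config = solver_config()) {
  v <- structure_value(belief, config)
  .decide(v, belief$counts, "structure")
}

#' Structure-policy action values over a whole count lattice
#'
#' One backward-induction pass from a root state to `total_depth`, returning
#' the per-action values of every lattice state within `record_depth`
#' increments of the root; each recorded state therefore has at least
#' `total_depth - record_depth` trials of lookahead. Useful for policy maps and
#' for comparing against the fixed-structure policies state by state.
#'
#' @param priors A [bandit_priors()]; `kappa0` is the coupling prior at the
#'   root.
#' @param config A [solver_config()].
#' @param total_depth Depth of the DP from the root.
#' @param record_depth Record values for states up to this many increments
#'   from the root.
#' @param root An [arm_counts()] root state (default all-zero counts).
#' @return A data.frame with columns `s1,f1,s2,f2,q1,q2`.
#' @export
structure_value_lattice <- function(priors = bandit_priors(),
                                    config = solver_config(),
                                    total_depth = config$horizon,
                                    record_depth = 0,
                                    root = arm_counts()) {
  stopifnot(inherits(priors, "bandit_priors"), record_depth < total_depth)
  m <- cpp_struct_q_lattice(root[["s1"]], root[["f1"]], root[["s2"]],
                            root[["f2"]], priors$kappa0,
                            priors$a1, priors$b1, priors$a2, priors$b2,
                            priors$a0, priors$b0, config$gamma,
                            as.integer(total_depth), as.integer(record_depth),
                            config$max_states)
  as.data.frame(m)
}

# internal: batched structure-policy Q values for rows of count states that
# share priors and gamma; kappa may vary per row
.struct_q_states <- function(states, kappa, priors, config) {
  cpp_struct_q_batch(states, kappa, priors$a1, priors$b1, priors$a2,
                     priors$b2, priors$a0, priors$b0, config$gamma,
                     config$horizon, config$max_states)
}
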