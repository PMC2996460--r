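#' Experiment configuration
#'
#' Describes the block/task/trial design: blocks of bandit tasks, one
#' environment type per block, reward probabilities drawn uniformly per task,
#' and geometric stopping. The defaults reproduce the study design: 2 blocks
#' of 16 tasks, one independent and one coupled, per-trial stop probability
#' 1/48 (mean stopping time 48).
#'
#' @param n_blocks Number of blocks.
#' @param tasks_per_block Tasks per block.
#' @param block_envs Character vector of length `n_blocks`, each
#'   `"independent"` or `"coupled"`.
#' @param stop_prob Per-trial stopping probability in (0, 1); stopping times
#'   are geometric with support 1, 2, ... and mean `1 / stop_prob`.
#' @param fixed_stop_time If non-NULL, every task lasts exactly this many
#'   trials instead of stopping geometrically (used for fixed-length learning
#'   simulations).
#' @param seed Optional integer seed making the schedule reproducible.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_blocks = 2, tasks_per_block = 16,
                              block_envs = c("independent", "coupled"),
                              stop_prob = 1 / 48, fixed_stop_time = NULL,
                              seed = NULL) {
  if (tasks_per_block < 1) stop("tasks_per_block must be >= 1", call. = FALSE)
  if (stop_prob <= 0 || stop_prob >= 1)
    stop("stop_prob must lie in (0, 1)", call. = FALSE)
  block_envs <- match.arg(block_envs, c("independent", "coupled"),
                          several.ok = TRUE)
  if (length(block_envs) != n_blocks)
    stop("block_envs must name one environment per block", call. = FALSE)
  if (!is.null(fixed_stop_time) && fixed_stop_time < 1)
    stop("fixed_stop_time must be >= 1", call. = FALSE)
  structure(list(n_blocks = as.integer(n_blocks),
                 tasks_per_block = as.integer(tasks_per_block),
                 block_envs = block_envs, stop_prob = stop_prob,
                 fixed_stop_time = fixed_stop_time, seed = seed),
            class = "experiment_config")
}

# run code under a temporary RNG state seeded with `seed` (NULL = current RNG)
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Draw a task schedule
#'
#' Samples, for every task, its true reward parameters (two independent
#' uniform probabilities, or one shared uniform probability whose complement
#' drives the other option in a coupled block) and its stopping time.
#'
#' @param config An [experiment_config()].
#' @return A data.frame with one row per task: `block`, `environment`, `task`
#'   (index within block), `p1`, `p2` (true per-option reward probabilities;
#'   in a coupled block `p2 = 1 - p1`), `stop_time`.
#' @export
make_schedule <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  .with_seed(config$seed, {
    blocks <- rep(seq_len(config$n_blocks), each = config$tasks_per_block)
    envs <- config$block_envs[blocks]
    n <- length(blocks)
    p1 <- stats::runif(n)
    p2 <- ifelse(envs == "coupled", 1 - p1, stats::runif(n))
    stop_time <- if (is.null(config$fixed_stop_time)) {
      stats::rgeom(n, config$stop_prob) + 1L
    } else rep(as.integer(config$fixed_stop_time), n)
    data.frame(block = blocks, environment = envs,
               task = rep(seq_len(config$tasks_per_block), config$n_blocks),
               p1 = p1, p2 = p2, stop_time = stop_time)
  })
}

#' Draw one binary reward from a task's generative model
#'
#' In an independent task each option pays with its own probability. In a
#' coupled task one latent Bernoulli draw with the shared probability fixes
#' both potential outcomes (option 1 pays the draw, option 2 its complement);
#' only the chosen option's outcome is revealed. Since only one arm is
#' observed per trial, the belief inference is identical under per-arm
#' complementary draws; the latent-draw reading is the strict form of "when
#' one option gives reward, the other will not".
#'
#' @param task A single row of a [make_schedule()] data.frame (or any list
#'   with `environment`, `p1`, `p2`).
#' @param action Chosen option, 1 or 2.
#' @return Integer reward, 0 or 1. Uses the current RNG stream.
#' @export
draw_reward <- function(task, action) {
  if (!action %in% c(1, 2)) stop("action must be 1 or 2", call. = FALSE)
  if (task$environment == "coupled") {
    x <- stats::runif(1) < task$p1
    as.integer(if (action == 1) x else !x)
  } else {
    p <- if (action == 1) task$p1 else task$p2
    as.integer(stats::runif(1) < p)
  }
}

# modal soft-max action with the shared tie-break rule
.q_modal_action <- function(qstate, beta, counts) {
  d <- beta * (qstate[1] - qstate[2])
  if (abs(d) <= .TIE_TOL) {
    pulls <- c(counts[["s1"]] + counts[["f1"]], counts[["s2"]] + counts[["f2"]])
    if (pulls[2] < pulls[1]) 2L else 1L
  } else if (d > 0) 1L else 2L
}

#' Simulate one agent through an experiment
#'
#' Plays every task of a schedule with one of the four decision models (or a
#' caller-supplied rule), recording each trial together with the
#' counts-before-choice snapshot. Beliefs (or the Q state) reset at task
#' boundaries; the coupling posterior is carried across tasks within a block
#' as the next task's coupling prior, and resets to `priors$kappa0` at block
#' boundaries.
#'
#' @param model `"structure"`, `"independent"`, `"coupled"`, `"qlearning"`, or
#'   a function `(belief, config) -> policy_decision`.
#' @param config An [experiment_config()]; ignored when `schedule` is given
#'   except for its environment labels embedded in the schedule.
#' @param priors A [bandit_priors()].
#' @param solver A [solver_config()] for the Bayesian policies.
#' @param qparams A [q_params()] for the Q-learning agent.
#' @param noise Probability in `[0, 0.5]` of replacing the policy's action
#'   with the other option.
#' @param schedule Optional pre-drawn schedule from [make_schedule()] (e.g. a
#'   shared schedule for a cohort); drawn from `config` when NULL.
#' @param agent_id Identifier written into the log.
#' @return A trial-log data.frame: `agent`, `block`, `environment`, `task`,
#'   `trial`, `action`, `reward`, the counts-before-choice snapshot `s1`,
#'   `f1`, `s2`, `f2`, and the task's true reward probabilities `p1`, `p2`.
#' @export
run_agent <- function(model = "structure", config = experiment_config(),
                      priors = bandit_priors(), solver = solver_config(),
                      qparams = q_params(), noise = 0, schedule = NULL,
                      agent_id = 1L) {
  if (noise < 0 || noise > 0.5) stop("noise must lie in [0, 0.5]",
                                     call. = FALSE)
  if (is.null(schedule)) schedule <- make_schedule(config)
  n_total <- sum(schedule$stop_time)
  out <- list(block = integer(n_total), environment = character(n_total),
              task = integer(n_total), trial = integer(n_total),
              action = integer(n_total), reward = integer(n_total),
              s1 = integer(n_total), f1 = integer(n_total),
              s2 = integer(n_total), f2 = integer(n_total),
              p1 = numeric(n_total), p2 = numeric(n_total))
  row <- 0L
  for (b in unique(schedule$block)) {
    kap <- priors$kappa0
    btasks <- schedule[schedule$block == b, , drop = FALSE]
    for (ti in seq_len(nrow(btasks))) {
      task <- btasks[ti, ]
      counts <- arm_counts()
      qstate <- c(qparams$q1_init, qparams$q2_init)
      pr_k <- priors; pr_k$kappa0 <- kap
      for (tr in seq_len(task$stop_time)) {
        action <- if (is.function(model)) {
          model(belief_state(counts, pr_k), solver)$action
        } else switch(model,
          structure   = structure_policy(belief_state(counts, pr_k),
                                         solver)$action,
          independent = independent_policy(belief_state(counts, pr_k),
                                           solver)$action,
          coupled     = coupled_policy(belief_state(counts, pr_k))$action,
          qlearning   = .q_modal_action(qstate, qparams$beta, counts),
          stop("unknown model: ", model, call. = FALSE))
        if (noise > 0 && stats::runif(1) < noise) action <- 3L - action
        reward <- draw_reward(task, action)
        row <- row + 1L
        out$block[row] <- task$block; out$environment[row] <- task$environment
        out$task[row] <- task$task; out$trial[row] <- tr
        out$action[row] <- action; out$reward[row] <- reward
        out$s1[row] <- counts[["s1"]]; out$f1[row] <- counts[["f1"]]
        out$s2[row] <- counts[["s2"]]; out$f2[row] <- counts[["f2"]]
        out$p1[row] <- task$p1; out$p2[row] <- task$p2
        counts <- update_counts(counts, action, reward)
        qstate <- td_update(qstate, action, reward, qparams)
      }
      pr_k$kappa0 <- kap
      kap <- coupling_posterior(counts, pr_k)
    }
  }
  cbind(data.frame(agent = agent_id), as.data.frame(out))
}

#' Simulate a cohort of agents
#'
#' Runs `n_agents` copies of a model through the experiment. By default all
#' agents share one schedule (the same reward probabilities and stopping
#' times), as in the study design; with `shared_schedule = FALSE` each agent
#' draws its own.
#'
#' @inheritParams run_agent
#' @param n_agents Number of agents.
#' @param shared_schedule Reuse one schedule for the whole cohort.
#' @param seed Optional integer seed for the whole cohort run.
#' @return A trial-log data.frame for all agents.
#' @export
run_cohort <- function(model = "structure", config = experiment_config(),
                       n_agents = 16, priors = bandit_priors(),
                       solver = solver_config(), qparams = q_params(),
                       noise = 0, shared_schedule = TRUE, seed = NULL) {
  .with_seed(seed, {
    schedule <- if (shared_schedule) make_schedule(config) else NULL
    logs <- lapply(seq_len(n_agents), function(a) {
      run_agent(model, config, priors, solver, qparams, noise,
                schedule = if (shared_schedule) schedule else
                  make_schedule(config),
                agent_id = a)
    })
    do.call(rbind, logs)
  })
}
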