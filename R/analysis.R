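# Trial-level behavioral analyses: choice features, model scoring, trial
# taxonomies, prediction-rate reports, coupling-belief curves and
# evidence-by-confidence choice surfaces.

# vectorized coupling posterior over rows of counts, with per-row prior kappa
.coupling_vec <- function(s1, f1, s2, f2, kappa, pr) {
  out <- kappa
  i <- kappa > 0 & kappa < 1
  if (any(i)) {
    lo <- log(kappa[i]) - log1p(-kappa[i]) +
      lbeta(pr$a0 + s1[i] + f2[i], pr$b0 + f1[i] + s2[i]) -
      lbeta(pr$a0, pr$b0) -
      (lbeta(pr$a1 + s1[i], pr$b1 + f1[i]) - lbeta(pr$a1, pr$b1)) -
      (lbeta(pr$a2 + s2[i], pr$b2 + f2[i]) - lbeta(pr$a2, pr$b2))
    out[i] <- stats::plogis(lo)
  }
  out
}

# vectorized tie-break: values matrix n x 2, pulls per option
.decide_vec <- function(v1, v2, pulls1, pulls2) {
  tie <- abs(v1 - v2) <= .TIE_TOL
  action <- ifelse(tie, ifelse(pulls2 < pulls1, 2L, 1L),
                   ifelse(v2 > v1, 2L, 1L))
  list(action = as.integer(action), tie = tie)
}

#' Evidence: smoothed log odds ratio of observed reward rates
#'
#' `log[(s_b + 1)/(f_b + 1)] - log[(s_w + 1)/(f_w + 1)]` where `b`/`w` are the
#' better and worse option (by true generative reward probability) and every
#' cell gets add-one smoothing, so the measure is finite even at zero counts.
#' Positive evidence means the observed frequencies favor the truly better
#' option.
#'
#' @param counts An [arm_counts()] object, or a data.frame with columns
#'   `s1,f1,s2,f2` (one row per trial).
#' @param better The better option (1 or 2), recycled over rows.
#' @return Numeric evidence value(s).
#' @examples
#' evidence(arm_counts(3, 1, 1, 1), better = 1) # log 2
#' @export
evidence <- function(counts, better) {
  x <- if (inherits(counts, "arm_counts"))
    as.data.frame(as.list(counts)) else counts
  sb <- ifelse(better == 1, x$s1, x$s2); fb <- ifelse(better == 1, x$f1, x$f2)
  sw <- ifelse(better == 1, x$s2, x$s1); fw <- ifelse(better == 1, x$f2, x$f1)
  log((sb + 1) / (fb + 1)) - log((sw + 1) / (fw + 1))
}

#' Confidence: smoothed log ratio of observation counts
#'
#' `log[(s_b + f_b + 2) / (s_w + f_w + 2)]` with the same add-one smoothing
#' per cell as [evidence()]. Positive confidence means the better option has
#' been observed more often, i.e. the evidence about it is the more reliable.
#'
#' @inheritParams evidence
#' @return Numeric confidence value(s).
#' @examples
#' confidence(arm_counts(3, 1, 1, 1), better = 1) # log(6/4)
#' @export
confidence <- function(counts, better) {
  x <- if (inherits(counts, "arm_counts"))
    as.data.frame(as.list(counts)) else counts
  nb <- ifelse(better == 1, x$s1 + x$f1, x$s2 + x$f2)
  nw <- ifelse(better == 1, x$s2 + x$f2, x$s1 + x$f1)
  log((nb + 2) / (nw + 2))
}

# replay a single agent's log to validate snapshots and recover the per-task
# coupling prior (carried over within a block, reset at block boundaries)
.replay_beliefs <- function(log, priors) {
  grp <- paste(log$agent, log$block, log$task, sep = "\r")
  new_task <- c(TRUE, grp[-1] != grp[-length(grp)])
  inc_s1 <- as.integer(log$action == 1 & log$reward == 1)
  inc_f1 <- as.integer(log$action == 1 & log$reward == 0)
  inc_s2 <- as.integer(log$action == 2 & log$reward == 1)
  inc_f2 <- as.integer(log$action == 2 & log$reward == 0)
  starts <- which(new_task)
  lens <- diff(c(starts, length(grp) + 1L))
  if (!identical(as.integer(log$trial),
                 unlist(lapply(lens, seq_len), use.names = FALSE))) {
    stop("corrupt trial log: trial indices not contiguous within tasks",
         call. = FALSE)
  }
  run0 <- function(x) { # cumulative count before each trial, per task
    cs <- cumsum(x)
    base <- rep(ifelse(starts == 1L, 0, cs[pmax(starts - 1L, 1L)]), lens)
    cs - x - base
  }
  exp_s1 <- run0(inc_s1); exp_f1 <- run0(inc_f1)
  exp_s2 <- run0(inc_s2); exp_f2 <- run0(inc_f2)
  bad <- which(exp_s1 != log$s1 | exp_f1 != log$f1 |
               exp_s2 != log$s2 | exp_f2 != log$f2)
  if (length(bad)) {
    stop(sprintf("corrupt trial log: counts snapshot inconsistent at row %d",
                 bad[1]), call. = FALSE)
  }
  # per-task coupling prior via sequential carry-over within each block
  task_rows <- starts
  task_last <- c(task_rows[-1] - 1L, nrow(log))
  kap_task <- numeric(length(task_rows))
  kap_after <- numeric(length(task_rows))
  pr <- priors
  for (i in seq_along(task_rows)) {
    first <- task_rows[i]
    if (i == 1 || log$block[first] != log$block[task_rows[i - 1]] ||
        log$agent[first] != log$agent[task_rows[i - 1]]) {
      kap <- priors$kappa0
    }
    kap_task[i] <- kap
    l <- task_last[i]
    fin_s1 <- exp_s1[l] + inc_s1[l]; fin_f1 <- exp_f1[l] + inc_f1[l]
    fin_s2 <- exp_s2[l] + inc_s2[l]; fin_f2 <- exp_f2[l] + inc_f2[l]
    kap <- .coupling_vec(fin_s1, fin_f1, fin_s2, fin_f2, kap, pr)
    kap_after[i] <- kap
  }
  kappa <- rep(kap_task, task_last - task_rows + 1L)
  # carried-out posterior at the end of each block
  blk_key <- paste(log$agent[task_rows], log$block[task_rows], sep = "\r")
  nt <- length(task_rows)
  blk_end_tasks <- which(c(blk_key[-1] != blk_key[-nt], TRUE))
  final <- data.frame(agent = log$agent[task_rows[blk_end_tasks]],
                      block = log$block[task_rows[blk_end_tasks]],
                      kappa_final = kap_after[blk_end_tasks])
  list(kappa_prior = kappa,
       coupling_belief = .coupling_vec(log$s1, log$f1, log$s2, log$f2,
                                       kappa, priors),
       final = final)
}

#' Replay the coupling-belief trajectory of a trial log
#'
#' Reconstructs, for every trial, the coupling prior of its task (the
#' posterior carried over from the previous task within the block) and the
#' coupling belief given the counts observed so far, plus the carried-out
#' posterior at the end of each block. Also validates the log's snapshot
#' consistency.
#'
#' @param log A trial log (see [run_agent()]).
#' @param priors A [bandit_priors()].
#' @return A list: `kappa_prior` and `coupling_belief` (per trial), and
#'   `final` (data.frame `agent`, `block`, `kappa_final`).
#' @export
coupling_beliefs <- function(log, priors = bandit_priors()) {
  .replay_beliefs(log, priors)
}

# per-agent Q-learning modal predictions
.q_predictions <- function(log, qp) {
  n <- nrow(log)
  pred <- integer(n); tie <- logical(n)
  grp <- paste(log$block, log$task, sep = "\r")
  new_task <- c(TRUE, grp[-1] != grp[-length(grp)])
  q1 <- qp$q1_init; q2 <- qp$q2_init
  for (t in seq_len(n)) {
    if (new_task[t]) { q1 <- qp$q1_init; q2 <- qp$q2_init }
    d <- qp$beta * (q1 - q2)
    if (abs(d) <= .TIE_TOL) {
      tie[t] <- TRUE
      pulls1 <- log$s1[t] + log$f1[t]; pulls2 <- log$s2[t] + log$f2[t]
      pred[t] <- if (pulls2 < pulls1) 2L else 1L
    } else pred[t] <- if (d > 0) 1L else 2L
    target <- log$reward[t] + qp$gamma_q * max(q1, q2)
    if (log$action[t] == 1) q1 <- q1 + qp$alpha * (target - q1)
    else q2 <- q2 + qp$alpha * (target - q2)
  }
  list(pred = pred, tie = tie)
}

#' Score the four decision models on every trial of a log
#'
#' Replays a trial log, validates the counts snapshots, reconstructs the
#' coupling belief trajectory (carried across tasks within a block), and
#' computes every model's decision from each trial's counts-before-choice
#' snapshot, together with the trial features and taxonomies used by the
#' downstream analyses.
#'
#' @param log A trial log (see [run_agent()]); must contain true reward
#'   probabilities `p1`, `p2` per trial (written by the simulator) so the
#'   better option is defined.
#' @param priors A [bandit_priors()] shared by all Bayesian models.
#' @param solver A [solver_config()].
#' @param qparams Q-learning parameters: a [q_params()] applied to every
#'   agent, a named list of `q_params` keyed by agent id, or NULL to fit each
#'   agent by [fit_qlearning()] first.
#' @param high_count_threshold Minimum number of observations of the
#'   independent model's preferred option for a disagreeing choice to count
#'   as over-exploration.
#' @return The log with added columns: `coupling_belief`, `better`,
#'   `evidence`, `confidence`; per model `m` in structure, independent,
#'   coupled, qlearning: `pred_m`, `tie_m`, `correct_m` (1/0, ties 0.5);
#'   `diagnostic`, `exploration` (`"under"`, `"over"`, `"none"`),
#'   `task_learning`.
#' @export
score_models <- function(log, priors = bandit_priors(),
                         solver = solver_config(), qparams = NULL,
                         high_count_threshold = 8) {
  stopifnot(nrow(log) >= 1)
  need <- c("agent", "block", "environment", "task", "trial", "action",
            "reward", "s1", "f1", "s2", "f2", "p1", "p2")
  miss <- setdiff(need, names(log))
  if (length(miss)) stop("trial log lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bel <- .replay_beliefs(log, priors)
  out <- log
  out$coupling_belief <- bel$coupling_belief
  out$better <- ifelse(log$p2 > log$p1, 2L, 1L)
  out$evidence <- evidence(log, out$better)
  out$confidence <- confidence(log, out$better)

  pulls1 <- log$s1 + log$f1; pulls2 <- log$s2 + log$f2
  n <- pulls1 + pulls2

  # fixed coupled model (myopic posterior means of the shared parameter)
  vc1 <- (priors$a0 + log$s1 + log$f2) / (priors$a0 + priors$b0 + n)
  vc2 <- (priors$b0 + log$f1 + log$s2) / (priors$a0 + priors$b0 + n)
  dc <- .decide_vec(vc1, vc2, pulls1, pulls2)

  # fixed independent model (Gittins indices, computed once per unique state)
  ga <- c(priors$a1 + log$s1, priors$a2 + log$s2)
  gb <- c(priors$b1 + log$f1, priors$b2 + log$f2)
  key <- paste(ga, gb)
  u <- !duplicated(key)
  gidx <- gittins_index(ga[u], gb[u], solver)[match(key, key[u])]
  vi1 <- gidx[seq_len(nrow(log))]
  vi2 <- gidx[nrow(log) + seq_len(nrow(log))]
  di <- .decide_vec(vi1, vi2, pulls1, pulls2)

  # structure-learning model (belief-state DP per trial, batched)
  qs <- .struct_q_states(cbind(log$s1, log$f1, log$s2, log$f2),
                         bel$kappa_prior, priors, solver)
  ds <- .decide_vec(qs[, 1], qs[, 2], pulls1, pulls2)

  # Q-learning (per-agent replay with fitted or supplied parameters)
  pq <- integer(nrow(log)); tq <- logical(nrow(log))
  for (ag in unique(log$agent)) {
    rows <- which(log$agent == ag)
    qp <- if (is.null(qparams)) {
      fit_qlearning(log[rows, ])$params
    } else if (inherits(qparams, "q_params")) qparams
    else qparams[[as.character(ag)]]
    if (is.null(qp)) stop("no q_params for agent ", ag, call. = FALSE)
    r <- .q_predictions(log[rows, ], qp)
    pq[rows] <- r$pred; tq[rows] <- r$tie
  }

  preds <- list(structure = ds, independent = di, coupled = dc,
                qlearning = list(pred = pq, tie = tq))
  for (m in names(preds)) {
    p <- preds[[m]]
    a <- if (is.null(p$action)) p$pred else p$action
    out[[paste0("pred_", m)]] <- a
    out[[paste0("tie_", m)]] <- p$tie
    out[[paste0("correct_", m)]] <-
      ifelse(p$tie, 0.5, as.numeric(a == log$action))
  }
  pm <- cbind(out$pred_structure, out$pred_independent, out$pred_coupled,
              out$pred_qlearning)
  out$diagnostic <- rowSums(pm != pm[, 1]) > 0
  out$exploration <- classify_exploration(out, high_count_threshold)
  # a clear three-way configuration: both fixed models commit to one action
  # and the structure model commits to the other (no value ties involved)
  out$task_learning <- out$pred_independent == out$pred_coupled &
    out$pred_structure != out$pred_independent &
    !out$tie_independent & !out$tie_coupled & !out$tie_structure
  out
}

#' Classify disagreements with the independent model as under- or
#' over-exploration
#'
#' On independent-environment trials where the recorded choice differs from
#' the independent (Gittins) model: if the model picked the option with the
#' lower smoothed reward proportion — an information-seeking pick the subject
#' declined — the trial is under-exploration; if the model picked the
#' higher-proportion option and that option has already been observed at
#' least `high_count_threshold` times — the subject persisted with a clearly
#' worse option — it is over-exploration; anything else is `"none"`.
#'
#' @param scored A scored log (from [score_models()]), or any data.frame with
#'   columns `environment`, `action`, `pred_independent`, `s1,f1,s2,f2`.
#' @param high_count_threshold Observation-count cutoff for "clearly worse".
#' @return Character vector: `"under"`, `"over"` or `"none"` per trial.
#' @export
classify_exploration <- function(scored, high_count_threshold = 8) {
  prop1 <- (scored$s1 + 1) / (scored$s1 + scored$f1 + 2)
  prop2 <- (scored$s2 + 1) / (scored$s2 + scored$f2 + 2)
  mp <- scored$pred_independent
  mp_prop <- ifelse(mp == 1, prop1, prop2)
  ot_prop <- ifelse(mp == 1, prop2, prop1)
  mp_pulls <- ifelse(mp == 1, scored$s1 + scored$f1, scored$s2 + scored$f2)
  applicable <- scored$environment == "independent" & scored$action != mp
  cls <- rep("none", nrow(scored))
  cls[applicable & mp_prop < ot_prop] <- "under"
  cls[applicable & mp_prop > ot_prop &
        mp_pulls >= high_count_threshold] <- "over"
  cls
}

#' Select task-learning trials
#'
#' Trials on which both fixed-structure models agree with each other while
#' the structure-learning model chooses the opposite option — all three
#' committing without value ties: the structure model's choice on such a
#' trial is attributable purely to reducing structure uncertainty.
#'
#' @param scored A scored log from [score_models()].
#' @return The subset of rows that are task-learning trials.
#' @export
task_learning_trials <- function(scored) {
  scored[scored$task_learning, , drop = FALSE]
}

# trial subsets used by the report
.subset_masks <- function(scored) {
  list(overall = rep(TRUE, nrow(scored)),
       diagnostic = scored$diagnostic,
       under_exploration = scored$exploration == "under",
       over_exploration = scored$exploration == "over",
       task_learning = scored$task_learning,
       independent_env = scored$environment == "independent",
       coupled_env = scored$environment == "coupled")
}

#' Prediction rates per model with pairwise exact binomial comparisons
#'
#' For every model and trial subset, the mean per-trial score (1 when the
#' model's modal action matches the recorded action, 0.5 on value ties, 0
#' otherwise). Model pairs are compared with a two-sided exact binomial test
#' restricted to trials where the two models disagree (and neither ties):
#' there, exactly one of the two matches the recorded choice, so under the
#' null both are equally good and the match count is Binomial(n, 0.5).
#'
#' @param scored A scored log from [score_models()].
#' @param models Models to include.
#' @return A list of class `prediction_report`: `rates` (model, subset, n,
#'   rate) and `tests` (model_a, model_b, subset, n_disagree, wins_a,
#'   p_value; `p_value` is NA when the models never disagree on the subset).
#' @export
prediction_report <- function(scored,
                              models = c("structure", "independent",
                                         "coupled", "qlearning")) {
  stopifnot(nrow(scored) >= 1)
  masks <- .subset_masks(scored)
  rates <- do.call(rbind, lapply(names(masks), function(s) {
    m <- masks[[s]]
    data.frame(model = models, subset = s, n = sum(m),
               rate = vapply(models, function(mo)
                 if (sum(m) == 0) NA_real_
                 else mean(scored[[paste0("correct_", mo)]][m]),
                 numeric(1)))
  }))
  pairs <- utils::combn(models, 2)
  tests <- do.call(rbind, lapply(names(masks), function(s) {
    m <- masks[[s]]
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      dis <- m & scored[[paste0("pred_", a)]] !=
        scored[[paste0("pred_", b)]] &
        !scored[[paste0("tie_", a)]] & !scored[[paste0("tie_", b)]]
      nd <- sum(dis)
      wins <- sum(scored[[paste0("correct_", a)]][dis] == 1)
      p <- if (nd == 0) NA_real_ else
        stats::binom.test(wins, nd, 0.5)$p.value
      data.frame(model_a = a, model_b = b, subset = s, n_disagree = nd,
                 wins_a = wins, p_value = p)
    }))
  }))
  structure(list(rates = rates, tests = tests), class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("Prediction rates:\n")
  print(utils::head(
    stats::reshape(x$rates, idvar = "subset", timevar = "model",
                   direction = "wide"), 20), row.names = FALSE)
  cat("\nPairwise exact binomial tests (diagnostic trials):\n")
  print(x$tests[x$tests$subset == "diagnostic", ], row.names = FALSE)
  invisible(x)
}

#' Better-option choice fraction as a function of coupling belief
#'
#' Bins trials by the coupling belief computed from the reward history, and
#' within each bin computes the fraction of choices to the truly better
#' option for the subject/agent and for each model's (tie-broken) predicted
#' actions; then the
#' Pearson correlation between the subject's curve and each model's over
#' non-empty bins.
#'
#' @param scored A scored log from [score_models()].
#' @param n_bins Number of equal-width bins on `[0, 1]`.
#' @param diagnostic_only Restrict to diagnostic trials.
#' @param models Models to include.
#' @return A list: `curve` (bin, midpoint, n, `subject`, one column per
#'   model) and `correlations` (named numeric).
#' @export
coupling_belief_curve <- function(scored, n_bins = 10,
                                  diagnostic_only = TRUE,
                                  models = c("structure", "independent",
                                             "coupled", "qlearning")) {
  stopifnot(n_bins >= 2)
  d <- if (diagnostic_only) scored[scored$diagnostic, , drop = FALSE] else
    scored
  bins <- pmin(n_bins, pmax(1, ceiling(d$coupling_belief * n_bins +
                                         1e-12)))
  frac_better <- function(act) {
    tapply(as.numeric(act == d$better), factor(bins, levels = seq_len(n_bins)),
           mean)
  }
  curve <- data.frame(bin = seq_len(n_bins),
                      midpoint = (seq_len(n_bins) - 0.5) / n_bins,
                      n = as.integer(table(factor(bins,
                                                  levels = seq_len(n_bins)))))
  curve$subject <- as.numeric(frac_better(d$action))
  for (m in models) {
    curve[[m]] <- as.numeric(frac_better(d[[paste0("pred_", m)]]))
  }
  ok <- curve$n > 0
  correlations <- vapply(models, function(m)
    suppressWarnings(stats::cor(curve$subject[ok], curve[[m]][ok])),
    numeric(1))
  list(curve = curve, correlations = correlations)
}

#' Better-option choice fractions over the evidence-by-confidence plane
#'
#' On diagnostic trials, bins the (evidence, confidence) features and
#' computes the empirical probability of choosing the truly better option
#' per cell, for the subject and each model. Cells with no trials are absent
#' from the result.
#'
#' @param scored A scored log from [score_models()].
#' @param evidence_breaks,confidence_breaks Monotone bin edges (the outer
#'   edges may be infinite).
#' @param models Models to include.
#' @return A data.frame with one row per non-empty cell: `evidence_bin`,
#'   `confidence_bin` (factor labels), `n`, `subject`, one column per model.
#' @export
choice_surface <- function(scored,
                           evidence_breaks = c(-Inf, -2, -1, -0.5, 0, 0.5, 1,
                                               2, Inf),
                           confidence_breaks = c(-Inf, -1.5, -0.75, 0, 0.75,
                                                 1.5, Inf),
                           models = c("structure", "independent", "coupled",
                                      "qlearning")) {
  stopifnot(!is.unsorted(evidence_breaks), !is.unsorted(confidence_breaks))
  d <- scored[scored$diagnostic, , drop = FALSE]
  eb <- cut(d$evidence, evidence_breaks, include.lowest = TRUE)
  cb <- cut(d$confidence, confidence_breaks, include.lowest = TRUE)
  cell <- interaction(eb, cb, drop = TRUE, sep = " x ")
  agg <- function(v) as.numeric(tapply(v, cell, mean))
  out <- data.frame(evidence_bin = tapply(as.character(eb), cell, `[`, 1),
                    confidence_bin = tapply(as.character(cb), cell, `[`, 1),
                    n = as.integer(table(cell)))
  out$subject <- agg(as.numeric(d$action == d$better))
  for (m in models) {
    out[[m]] <- agg(as.numeric(d[[paste0("pred_", m)]] == d$better))
  }
  rownames(out) <- NULL
  out
}
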