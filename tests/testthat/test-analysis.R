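test_that("evidence and confidence use add-one smoothing and are
           antisymmetric under the option swap", {
  expect_equal(evidence(arm_counts(1, 1, 1, 1), 1), 0)
  expect_equal(evidence(arm_counts(3, 1, 1, 1), 1), log(2))
  expect_equal(confidence(arm_counts(1, 2, 1, 2), 1), 0)
  expect_equal(confidence(arm_counts(3, 1, 1, 1), 1), log(6 / 4))
  set.seed(14)
  for (i in 1:10) {
    ct <- sample(0:9, 4, replace = TRUE)
    a <- do.call(arm_counts, as.list(ct))
    b <- arm_counts(ct[3], ct[4], ct[1], ct[2])
    expect_equal(evidence(a, 1), evidence(b, 2)) # arm swap with label swap
    expect_equal(evidence(a, 1), -evidence(a, 2))
    expect_equal(confidence(a, 1), -confidence(a, 2))
  }
})

test_that("scoring replays a log consistently: ties at empty counts, the
           diagnostic flag, and snapshot validation", {
  solver <- solver_config(horizon = 20)
  cfg <- experiment_config(n_blocks = 2, tasks_per_block = 2, seed = 17)
  set.seed(17)
  log <- run_agent("coupled", cfg)
  sc <- score_models(log, solver = solver, qparams = q_params())
  first <- sc[sc$trial == 1, ]
  for (m in c("structure", "independent", "coupled", "qlearning")) {
    expect_true(all(first[[paste0("tie_", m)]]))
    expect_true(all(first[[paste0("correct_", m)]] == 0.5))
  }
  expect_true(all(!first$diagnostic))
  # on the constructed disagreement state, coupled and independent differ
  dis <- sc[sc$pred_coupled != sc$pred_independent, ]
  expect_true(all(dis$diagnostic))
  # corrupt snapshot is caught
  bad <- log
  bad$s1[5] <- bad$s1[5] + 1L
  expect_error(score_models(bad, solver = solver, qparams = q_params()),
               "corrupt")
})

test_that("the fixed models disagree on the constructed policy-switch
           state", {
  cfg <- solver_config()
  st <- belief_state(arm_counts(1, 0, 5, 2))
  expect_equal(coupled_policy(st)$action, 2L)
  expect_equal(independent_policy(st, cfg)$action, 1L)
})

test_that("exploration classes follow the under/over definitions", {
  solver <- solver_config()
  # under: the model's pick is the lower-proportion (less-sampled) option
  stub <- data.frame(environment = "independent", action = 1L,
                     pred_independent = 2L, s1 = 4L, f1 = 4L, s2 = 0L,
                     f2 = 1L)
  expect_equal(classify_exploration(stub), "under")
  # over: the model's pick is the clearly better, well-sampled option
  stub2 <- data.frame(environment = "independent", action = 2L,
                      pred_independent = 1L, s1 = 6L, f1 = 2L, s2 = 1L,
                      f2 = 7L)
  expect_equal(classify_exploration(stub2), "over")
  # below the high-count threshold it is not over-exploration
  expect_equal(classify_exploration(stub2, high_count_threshold = 10), "none")
  # agreement with the model gates everything off
  stub3 <- stub; stub3$action <- 2L
  expect_equal(classify_exploration(stub3), "none")
  # coupled-environment trials are never classified
  stub4 <- stub; stub4$environment <- "coupled"
  expect_equal(classify_exploration(stub4), "none")
})

test_that("task-learning trials are exactly those where the structure model
           opposes the agreeing fixed models", {
  df <- make_scored_stub(pred_a = c(1L, 2L, 1L), pred_b = c(1L, 2L, 2L),
                         action = c(1L, 1L, 2L))
  # structure==coupled==pred_a, independent==qlearning==pred_b
  df$task_learning <- df$pred_independent == df$pred_coupled &
    df$pred_structure != df$pred_independent
  got <- task_learning_trials(df)
  expect_equal(nrow(got), 0L) # structure equals coupled everywhere here
  df2 <- df
  df2$pred_structure <- c(2L, 2L, 1L)
  df2$pred_independent <- c(1L, 2L, 2L)
  df2$pred_coupled <- c(1L, 2L, 2L)
  df2$task_learning <- df2$pred_independent == df2$pred_coupled &
    df2$pred_structure != df2$pred_independent
  expect_equal(which(df2$task_learning), c(1L, 3L))
})

test_that("the prediction report reproduces the exact binomial tail and
           marks identical models undefined", {
  pred_a <- rep(1L, 10)
  pred_b <- rep(2L, 10)
  action <- c(rep(1L, 9), 2L) # A wins 9 of 10 disagreements
  df <- make_scored_stub(pred_a, pred_b, action)
  rep <- prediction_report(df)
  t_ab <- rep$tests[rep$tests$model_a == "structure" &
                      rep$tests$model_b == "independent" &
                      rep$tests$subset == "overall", ]
  expect_equal(t_ab$n_disagree, 10L)
  expect_equal(t_ab$wins_a, 9L)
  expect_equal(t_ab$p_value, 2 * (choose(10, 9) + choose(10, 10)) / 2^10,
               tolerance = 1e-12)
  # structure and coupled are identical in the stub: undefined comparison
  t_ac <- rep$tests[rep$tests$model_a == "structure" &
                      rep$tests$model_b == "coupled" &
                      rep$tests$subset == "overall", ]
  expect_equal(t_ac$n_disagree, 0L)
  expect_true(is.na(t_ac$p_value))
  # a model matching every action has rate 1
  r <- rep$rates[rep$rates$subset == "overall", ]
  expect_equal(r$rate[r$model == "structure"], 0.9)
  df_perfect <- make_scored_stub(action, pred_b, action)
  rp <- prediction_report(df_perfect)
  expect_equal(rp$rates$rate[rp$rates$model == "structure" &
                               rp$rates$subset == "overall"], 1.0)
})

test_that("subset prediction rates recombine to the overall rate by trial
           counts", {
  solver <- solver_config(horizon = 20)
  cfg <- experiment_config(n_blocks = 2, tasks_per_block = 3, seed = 23)
  set.seed(23)
  log <- run_agent("structure", cfg, solver = solver, noise = 0.1)
  sc <- score_models(log, solver = solver, qparams = q_params())
  rep <- prediction_report(sc)
  r <- rep$rates
  for (m in c("structure", "coupled")) {
    overall <- r$rate[r$model == m & r$subset == "overall"]
    ie <- r[r$model == m & r$subset == "independent_env", ]
    ce <- r[r$model == m & r$subset == "coupled_env", ]
    expect_equal(overall,
                 (ie$rate * ie$n + ce$rate * ce$n) / (ie$n + ce$n))
  }
})

test_that("an agent identical to a model correlates perfectly with it on the
           coupling-belief curve and choice surface", {
  solver <- solver_config(horizon = 20)
  cfg <- experiment_config(n_blocks = 2, tasks_per_block = 4, seed = 29)
  set.seed(29)
  log <- run_agent("structure", cfg, solver = solver) # no noise
  sc <- score_models(log, solver = solver, qparams = q_params())
  expect_true(all(sc$pred_structure == sc$action))
  cbc <- coupling_belief_curve(sc)
  expect_equal(unname(cbc$correlations["structure"]), 1.0)
  surf <- choice_surface(sc)
  expect_equal(surf$subject, surf$structure)
})

test_that("a uniformly random agent sits near one half in every populated
           coupling-belief bin", {
  rand <- function(belief, config)
    structure(list(values = c(0, 0),
                   action = sample(1:2, 1), tie = FALSE,
                   model_id = "random"), class = "policy_decision")
  cfg <- experiment_config(n_blocks = 2, tasks_per_block = 8,
                           fixed_stop_time = 60, seed = 31)
  set.seed(31)
  log <- run_agent(rand, cfg)
  sc <- score_models(log, solver = solver_config(horizon = 10),
                     qparams = q_params())
  cbc <- coupling_belief_curve(sc, n_bins = 5, diagnostic_only = FALSE)
  big <- cbc$curve[cbc$curve$n >= 100, ]
  expect_true(all(abs(big$subject - 0.5) < 3 * sqrt(0.25 / big$n) + 0.02))
})
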