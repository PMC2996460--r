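test_that("Gittins index equals the posterior mean with no future and
           matches the lattice oracle when discounting", {
  cfg0 <- solver_config(gamma = 0)
  expect_equal(gittins_index(1, 1, cfg0), 0.5)
  expect_equal(gittins_index(3, 1, cfg0), 0.75)
  cfg9 <- solver_config(gamma = 0.9, gittins_horizon = 200,
                        index_tolerance = 1e-6)
  for (ab in list(c(1, 1), c(2, 3), c(5, 2), c(1, 6))) {
    expect_equal(gittins_index(ab[1], ab[2], cfg9),
                 oracle_gittins(ab[1], ab[2], 0.9), tolerance = 1e-4)
  }
  expect_error(gittins_index(0, 1, cfg9), "positive")
})

test_that("Gittins index carries an exploration bonus and is monotone in the
           pseudo-counts", {
  for (g in c(0.5, 0.9)) {
    cfg <- solver_config(gamma = g, gittins_horizon = 200)
    grid <- expand.grid(a = 1:10, b = 1:10)
    idx <- matrix(gittins_index(grid$a, grid$b, cfg), 10, 10)
    mean_ <- outer(1:10, 1:10, function(a, b) a / (a + b))
    expect_true(all(idx >= mean_ - 1e-9))
    expect_true(all(apply(idx, 2, diff) > -1e-9))   # increasing in a
    expect_true(all(apply(idx, 1, diff) < 1e-9))    # decreasing in b
  }
})

test_that("independent policy ranks options by Gittins index with the
           information-favoring tie-break", {
  cfg <- solver_config()
  d <- independent_policy(belief_state(arm_counts()), cfg)
  expect_true(d$tie)
  expect_equal(d$action, 1L)
  # a much-sampled failing arm loses to an unexplored arm
  d2 <- independent_policy(belief_state(arm_counts(0, 4, 0, 0)), cfg)
  expect_equal(d2$action, 2L)
  expect_lt(d2$values[1], d2$values[2])
  # values are the per-arm indices
  d3 <- independent_policy(belief_state(arm_counts(5, 1, 0, 0)), cfg)
  expect_equal(d3$values, c(gittins_index(6, 2, cfg),
                            gittins_index(1, 1, cfg)))
})

test_that("coupled value pools cross-option evidence and the coupled policy
           is myopic in it", {
  pr <- bandit_priors()
  expect_equal(coupled_value(arm_counts(), pr, 1), 0.5)
  expect_equal(coupled_value(arm_counts(2, 1, 0, 3), pr, 1), 0.75)
  expect_equal(coupled_value(arm_counts(0, 0, 4, 0), pr, 1), 1 / 6)
  expect_equal(coupled_value(arm_counts(0, 0, 4, 0), pr, 2), 5 / 6)
  expect_equal(coupled_policy(belief_state(arm_counts(2, 1, 0, 3)))$action, 1L)
  expect_equal(coupled_policy(belief_state(arm_counts(0, 2, 3, 0)))$action, 2L)
  expect_true(coupled_policy(belief_state(arm_counts(1, 1, 1, 1)))$tie)
})

test_that("structure values reduce to predictive rewards at horizon one and
           match the exhaustive history-tree oracle", {
  pr <- bandit_priors()
  ct <- arm_counts(3, 1, 1, 2)
  v1 <- structure_value(belief_state(ct, pr), solver_config(horizon = 1))
  expect_equal(unname(v1), c(predictive_reward(ct, pr, 1),
                             predictive_reward(ct, pr, 2)))
  v3 <- structure_value(belief_state(arm_counts(), pr),
                        solver_config(horizon = 3, gamma = 0.98))
  expect_equal(unname(v3), oracle_tree_values(arm_counts(), pr, 0.98, 3),
               tolerance = 1e-10)
  set.seed(5)
  for (i in 1:4) {
    ct <- do.call(arm_counts, as.list(sample(0:4, 4, replace = TRUE)))
    prs <- bandit_priors(kappa0 = runif(1, 0.1, 0.9))
    h <- sample(2:5, 1); g <- runif(1, 0.5, 0.99)
    v <- structure_value(belief_state(ct, prs),
                         solver_config(horizon = h, gamma = g))
    expect_equal(unname(v), oracle_tree_values(ct, prs, g, h),
                 tolerance = 1e-10)
  }
})

test_that("structure value dominates the myopic value", {
  set.seed(9)
  for (i in 1:10) {
    ct <- do.call(arm_counts, as.list(sample(0:10, 4, replace = TRUE)))
    pr <- bandit_priors(kappa0 = runif(1))
    v <- structure_value(belief_state(ct, pr), solver_config(horizon = 20))
    expect_gte(max(v), max(predictive_reward(ct, pr, 1),
                           predictive_reward(ct, pr, 2)))
  }
})

test_that("the structure policy collapses onto the fixed policies at
           degenerate coupling priors", {
  cfg <- solver_config(horizon = 40)
  set.seed(13)
  for (i in 1:8) {
    ct <- do.call(arm_counts, as.list(sample(0:12, 4, replace = TRUE)))
    s <- structure_policy(belief_state(ct, bandit_priors(kappa0 = 1)), cfg)
    expect_equal(s$action, coupled_policy(belief_state(ct))$action)
  }
  # independent limit needs deeper lookahead for exact agreement on near-ties;
  # these states are far from ties
  for (ct in list(arm_counts(0, 4, 0, 0), arm_counts(5, 1, 0, 2),
                  arm_counts(1, 0, 5, 2))) {
    s <- structure_policy(belief_state(ct, bandit_priors(kappa0 = 0)),
                          solver_config(horizon = 80))
    expect_equal(s$action,
                 independent_policy(belief_state(ct), solver_config())$action)
  }
})

test_that("an over-budget lattice signals a capacity error naming the
           budget", {
  expect_error(structure_value(belief_state(),
                               solver_config(horizon = 400,
                                             max_states = 1e5)),
               "budget")
})

test_that("policy decisions expose values, tie flag and model identity", {
  d <- structure_policy(belief_state(), solver_config(horizon = 5))
  expect_s3_class(d, "policy_decision")
  expect_true(d$tie)
  expect_identical(d$model_id, "structure")
  expect_equal(d$action, which.max(d$values))
})
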