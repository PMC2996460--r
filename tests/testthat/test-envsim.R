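test_that("the default schedule reproduces the study design arithmetic", {
  sch <- make_schedule(experiment_config(seed = 1))
  expect_equal(nrow(sch), 32)
  expect_equal(as.vector(table(sch$environment)), c(16, 16))
  expect_true(all(sch$stop_time >= 1))
  expect_true(all(sch$p1 >= 0 & sch$p1 <= 1))
  # coupled tasks share one parameter
  cpl <- sch[sch$environment == "coupled", ]
  expect_equal(cpl$p2, 1 - cpl$p1)
  # determinism under a fixed seed
  expect_identical(sch, make_schedule(experiment_config(seed = 1)))
  expect_false(identical(sch$p1,
                         make_schedule(experiment_config(seed = 2))$p1))
})

test_that("geometric stopping has the configured mean", {
  cfg <- experiment_config(tasks_per_block = 600, stop_prob = 1 / 10,
                           seed = 4)
  st <- make_schedule(cfg)$stop_time
  se <- sqrt(0.9) / 0.1 / sqrt(length(st))
  expect_lt(abs(mean(st) - 10), 3 * se)
})

test_that("reward draws respect each environment's generative model", {
  expect_equal(draw_reward(list(environment = "coupled", p1 = 1, p2 = 0), 1),
               1L)
  expect_equal(draw_reward(list(environment = "coupled", p1 = 1, p2 = 0), 2),
               0L)
  expect_equal(draw_reward(list(environment = "independent", p1 = 1, p2 = 0),
                           2), 0L)
  set.seed(10)
  task <- list(environment = "coupled", p1 = 0.7, p2 = 0.3)
  r <- replicate(10000, draw_reward(task, 2))
  expect_lt(abs(mean(r) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("trial logs conserve record counts and are seed-reproducible", {
  cfg <- experiment_config(n_blocks = 2, tasks_per_block = 3, seed = 2)
  sch <- make_schedule(cfg)
  set.seed(21)
  log <- run_agent("coupled", cfg, schedule = sch)
  expect_equal(nrow(log), sum(sch$stop_time))
  per_task <- tapply(log$trial, paste(log$block, log$task), length)
  expect_equal(sort(as.integer(per_task)), sort(sch$stop_time))
  set.seed(21)
  log2 <- run_agent("coupled", cfg, schedule = sch)
  expect_identical(log, log2)
})

test_that("full choice noise makes actions fair coin flips", {
  always1 <- function(belief, config)
    structure(list(values = c(1, 0), action = 1L, tie = FALSE,
                   model_id = "const"), class = "policy_decision")
  cfg <- experiment_config(n_blocks = 1, tasks_per_block = 6,
                           block_envs = "independent", fixed_stop_time = 80,
                           seed = 3)
  set.seed(30)
  log <- run_agent(always1, cfg, noise = 0.5)
  p2 <- mean(log$action == 2)
  expect_lt(abs(p2 - 0.5), 3 * sqrt(0.25 / nrow(log)))
})

test_that("a structure agent certain of coupling makes the coupled agent's
           choices", {
  cfg <- experiment_config(n_blocks = 1, tasks_per_block = 2,
                           block_envs = "coupled", fixed_stop_time = 25,
                           seed = 12)
  sch <- make_schedule(cfg)
  pr1 <- bandit_priors(kappa0 = 1)
  set.seed(40)
  a <- run_agent("structure", cfg, priors = pr1,
                 solver = solver_config(horizon = 20), schedule = sch)
  set.seed(40)
  b <- run_agent("coupled", cfg, priors = pr1, schedule = sch)
  expect_identical(a$action, b$action)
  expect_identical(a$reward, b$reward)
})

test_that("a shared-schedule cohort exposes every agent to the same tasks", {
  cfg <- experiment_config(n_blocks = 2, tasks_per_block = 2)
  co <- run_cohort("coupled", cfg, n_agents = 3, seed = 77)
  byagent <- split(co[, c("block", "task", "p1", "p2")], co$agent)
  sch1 <- unique(byagent[[1]])
  for (k in 2:3) expect_equal(unique(byagent[[k]]), sch1,
                              ignore_attr = TRUE)
  # trial totals equal across agents (same stopping times)
  expect_equal(length(unique(table(co$agent))), 1L)
})
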