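test_that("an empty generation plays no games but still reproduces", {
  p <- tiny_params(games_per_gen = 0L, generations = 1L)
  set.seed(421)
  pop <- make_pop(fusion = runif(12), personal_rep = 2L)
  pop$payoff <- runif(12)
  step <- run_generation(pop, p, new_metrics())
  expect_equal(step$metrics$cum_games, 0)
  expect_equal(step$metrics$cum_donations, 0)
  expect_identical(step$pop$personal_rep, rep(0L, 12))
  expect_equal(step$pop$payoff, rep(0, 12))
})

test_that("an all-defector population never donates", {
  p <- tiny_params(games_per_gen = 200L, generations = 1L,
                   mutation_rate = 0)
  init <- make_pop(fusion = runif(12), rule_s = 0L, rule_u = 0L,
                   rule_d = 0L)
  out <- run_model(p, init = init)
  expect_equal(out$metrics$cum_donations, 0)
  expect_equal(out$metrics$avg_cooperation, 0)
})

test_that("unfused donors with the dominant rule match a brute-force trace", {
  # all fusion zero, rules (1,1,0): donations happen on similarity or
  # upward comparison of integer personal reputations; donors that get
  # ahead legitimately defect downward, so the donation count is below m.
  # An independent naive replay of the draw order gives the exact count.
  p <- sim_params(n_agents = 10L, games_per_gen = 300L, generations = 1L,
                  mutation_rate = 0, mutate_fusion = FALSE, seed = 5L)
  init <- make_pop(fusion = rep(0, 10), rule_s = 1L, rule_u = 1L,
                   rule_d = 0L)
  out <- run_model(p, init = init)

  set.seed(5)
  rep_ <- integer(10)
  donations <- 0L
  for (g in 1:300) {
    i <- 1L + floor(runif(1) * 10)
    runif(1)  # in-group gate (S = 0)
    t <- 1L + floor(runif(1) * 9)
    j <- if (t >= i) t + 1L else t
    if (rep_[j] >= rep_[i]) {  # similar or upward for (1,1,0)
      rep_[i] <- min(5L, rep_[i] + 1L)
      donations <- donations + 1L
    } else {
      # downward: legitimate defection, no reputation change
    }
  }
  expect_equal(out$metrics$cum_donations, donations)
  expect_gt(donations, 0L)
  expect_lt(donations, 300L)
  expect_identical(out$trajectory$group_rep, 0L)
})

test_that("cumulative metrics stay within their bounds along a run", {
  p <- tiny_params(generations = 12L, ostracism_type = 3L,
                   s_policy = "fusion", err_perception = 0.2,
                   err_execution = 0.2)
  out <- run_model(p)
  tr <- out$trajectory
  expect_true(all(tr$avg_coop >= 0 & tr$avg_coop <= 1))
  expect_true(all(tr$avg_fusion >= 0 & tr$avg_fusion <= 1))
  expect_true(all(tr$group_rep >= -5L & tr$group_rep <= 5L))
  expect_true(all(abs(diff(tr$avg_fusion)) <= 1 / seq(2, 12)))
})

test_that("a single-seed experiment equals its one run and reruns are identical", {
  p <- tiny_params(ostracism_type = 1L, s_policy = 0.5)
  ex1 <- run_experiment(p, n_seeds = 1L)
  single <- run_model(p)
  expect_equal(ex1$avg_cooperation, single$metrics$avg_cooperation)
  expect_equal(ex1$avg_fusion, single$metrics$avg_fusion)

  ex2 <- run_experiment(p, n_seeds = 3L)
  ex3 <- run_experiment(p, n_seeds = 3L)
  expect_identical(ex2$per_seed, ex3$per_seed)
  expect_identical(ex2$avg_trajectory, ex3$avg_trajectory)
})

test_that("run_model is deterministic given (params, seed)", {
  p <- tiny_params(ostracism_type = 3L, s_policy = "fusion",
                   err_perception = 0.1, err_execution = 0.1)
  a <- run_model(p)
  b <- run_model(p)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final_pop, b$final_pop)
})

test_that("simulation objects print, summarise and convert", {
  p <- tiny_params()
  out <- run_model(p)
  expect_output(print(out), "average cooperation")
  s <- summary(out)
  expect_s3_class(s, "summary.fusion_sim")
  expect_match(s$modal_rule, "^[01]{3}$")
  expect_s3_class(as.data.frame(out), "data.frame")
  ex <- run_experiment(p, n_seeds = 2L)
  expect_output(print(ex), "Seed-averaged")
  expect_identical(nrow(summary(ex)), 2L)
})
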