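test_that("fitness weights are shifted, normalised payoffs", {
  expect_equal(fitness_weights(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_equal(fitness_weights(c(5, 5, 5)), rep(1 / 3, 3))
  # negative payoffs shift by the worst payoff
  expect_equal(fitness_weights(c(-1, 0, 3)), c(0, 1 / 5, 4 / 5))
  # all-equal-after-shift degenerates to uniform
  expect_equal(fitness_weights(c(-2, -2)), c(0.5, 0.5))
  w <- fitness_weights(rnorm(20))
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1)
})

test_that("mutation flips rule bits and resamples fusion at the stated rate", {
  set.seed(411)
  expect_identical(mutate_agent(1L, 1L, 0L, 0.4, 0),
                   list(rule_s = 1L, rule_u = 1L, rule_d = 0L, fusion = 0.4))
  m1 <- mutate_agent(1L, 1L, 0L, 0.4, 1)
  expect_identical(m1[c("rule_s", "rule_u", "rule_d")],
                   list(rule_s = 0L, rule_u = 0L, rule_d = 1L))
  expect_false(m1$fusion == 0.4)
  # flip frequency matches the binomial expectation at mu = 0.01
  flips <- vapply(seq_len(50000), function(i) {
    mutate_agent(0L, 0L, 0L, 0.5, 0.01)$rule_s
  }, integer(1))
  expect_equal(mean(flips), 0.01, tolerance = 0.15)
})

test_that("roulette reproduction copies the fittest and resets state", {
  p <- tiny_params(ostracism_type = 0L, mutation_rate = 0)
  pop <- make_pop(fusion = runif(12), personal_rep = 3L, n_pos = 2L)
  pop$payoff <- c(10, rep(-1, 11))  # one agent holds all shifted weight?
  # after the shift by +1 the others have weight 0: everyone copies agent 1
  set.seed(412)
  child <- reproduce_population(pop, p)
  expect_identical(child$rule_s, rep(pop$rule_s[1], 12))
  expect_equal(child$fusion, rep(pop$fusion[1], 12))
  expect_identical(child$personal_rep, rep(0L, 12))
  expect_identical(child$n_pos, rep(0L, 12))
  expect_equal(child$payoff, rep(0, 12))
  expect_identical(child$group_rep, 0L)
})

test_that("reproduction-stage ostracism excludes a hypocritical top earner", {
  # agent 1: top payoff but zero contribution; the rest contributed fully.
  # With certain checks (f = 1, no errors) every other slot excludes agent
  # 1 and draws from the remainder.
  p <- tiny_params(ostracism_type = 2L, mutation_rate = 0)
  pop <- make_pop(fusion = rep(1, 12), rule_s = c(0L, rep(1L, 11)))
  pop$payoff <- c(10, rep(1, 11))
  pop$n_neg <- c(5L, rep(0L, 11))
  pop$n_pos <- c(0L, rep(5L, 11))
  set.seed(413)
  child <- reproduce_population(pop, p)
  # slots 2..12 can only have copied rule_s = 1; agent 1 may only
  # reproduce into its own slot (it does not check itself)
  expect_identical(child$rule_s[2:12], rep(1L, 11))
})

test_that("a monomorphic population stays monomorphic without mutation", {
  p <- tiny_params(ostracism_type = 0L, mutation_rate = 0,
                   games_per_gen = 40L, generations = 8L)
  init <- make_pop(fusion = rep(0.5, 12), rule_s = 1L, rule_u = 1L,
                   rule_d = 0L)
  out <- run_model(p, engine = "r", init = init)
  expect_identical(out$final_pop$rule_s, rep(1L, 12))
  expect_identical(out$final_pop$rule_u, rep(1L, 12))
  expect_identical(out$final_pop$rule_d, rep(0L, 12))
  expect_equal(out$final_pop$fusion, rep(0.5, 12))
})

test_that("selection is neutral under equal payoffs", {
  p <- tiny_params(ostracism_type = 0L, mutation_rate = 0)
  pop <- make_pop(fusion = seq(0.01, 0.99, length.out = 12))
  set.seed(414)
  copies <- integer(12)
  for (rep_i in 1:400) {
    child <- reproduce_population(pop, p)
    tab <- tabulate(match(child$fusion, pop$fusion), nbins = 12)
    copies <- copies + tab
  }
  # 400 x 12 slots, expected 400 per parent under neutrality
  expect_equal(copies / sum(copies), rep(1 / 12, 12), tolerance = 0.12)
})

test_that("population size is constant across generations", {
  p <- tiny_params(ostracism_type = 3L, s_policy = "fusion",
                   err_perception = 0.1)
  out <- run_model(p)
  expect_length(out$final_pop$fusion, p$n_agents)
  expect_length(out$final_pop$rule_s, p$n_agents)
})
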