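test_that("perceived reputation blends personal and group reputation by the target's fusion", {
  # fused observer: convex combination weighted by the target's fusion
  expect_equal(perceived_reputation(0.3, 0.5, 4, -2), 1.0)
  # unfused observer ignores the group entirely, whatever the target's fusion
  expect_equal(perceived_reputation(0, 0.9, 3, -5), 3)
  # unfused target collapses the blend to its personal reputation
  expect_equal(perceived_reputation(0.1, 0, -5, 5), -5)
})

test_that("perceived reputation stays between the personal and group reputations", {
  set.seed(401)
  for (k in 1:200) {
    f_obs <- runif(1)
    f_tgt <- runif(1)
    r_tgt <- sample(-5:5, 1)
    r_grp <- sample(-5:5, 1)
    v <- perceived_reputation(f_obs, f_tgt, r_tgt, r_grp)
    expect_gte(v, min(r_tgt, r_grp))
    expect_lte(v, max(r_tgt, r_grp))
  }
})

test_that("comparison classification partitions the view pairs", {
  expect_identical(classify_comparison(2, 2), "similar")
  expect_identical(classify_comparison(2, 3), "upward")
  expect_identical(classify_comparison(2.0, 1.5), "downward")
  # delta = 0 on real views: similarity is exact equality
  expect_identical(classify_comparison(4.3, 4.300000001), "upward")
  # every pair lands in exactly one class
  set.seed(402)
  v <- matrix(runif(200, -5, 5), ncol = 2)
  cls <- classify_comparison(v[, 1], v[, 2])
  expect_true(all(cls %in% c("upward", "similar", "downward")))
})

test_that("donation decisions agree with the exhaustive rule table", {
  tab <- decision_rule_table()
  expect_identical(nrow(tab), 24L)
  got <- donation_decision(tab$rule_s, tab$rule_u, tab$rule_d,
                           tab$comparison)
  expect_identical(unname(got), tab$donate)
  # the dominant strategy donates upward and on similarity, not downward
  expect_true(donation_decision(1, 1, 0, "upward"))
  expect_false(donation_decision(1, 1, 0, "downward"))
  expect_false(donation_decision(0, 0, 0, "similar"))
})

test_that("contribution ratio follows the counter arithmetic and is undefined without actions", {
  expect_equal(contribution_ratio(3, 1, 1), 0.8)
  expect_true(is.na(contribution_ratio(0, 0, 0)))
  expect_equal(contribution_ratio(0, 0, 4), 0)
  # brute-force check over all small counter triples
  for (np in 0:3) for (nu in 0:3) for (ng in 0:3) {
    got <- contribution_ratio(np, nu, ng)
    if (np + nu + ng == 0) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, (np + nu) / (np + nu + ng))
      expect_gte(got, 0)
      expect_lte(got, 1)
    }
  }
})

test_that("hypocrisy requires at least equal fusion and a lower perceived contribution", {
  expect_true(is_hypocrite(0.4, 0.6, 0.9, 0.5))
  expect_false(is_hypocrite(0.6, 0.4, 0.9, 0.1))  # fusion clause fails
  expect_false(is_hypocrite(0.4, 0.4, 0.9, 0.9))  # equal contribution
  # undefined ratios block the judgement entirely
  expect_false(is_hypocrite(0.4, 0.6, NA_real_, 0.5))
  expect_false(is_hypocrite(0.4, 0.6, 0.9, NA_real_))
})

test_that("hypocrisy is monotone in the target's perceived contribution", {
  set.seed(403)
  for (k in 1:100) {
    f_i <- runif(1); f_j <- runif(1); c_i <- runif(1)
    grid <- sort(runif(8))
    verdicts <- vapply(grid, function(cj) is_hypocrite(f_i, f_j, c_i, cj),
                       logical(1))
    # raising ctr_j can only switch TRUE -> FALSE, never back
    expect_true(all(diff(as.integer(verdicts)) <= 0))
  }
})

test_that("perception error passes truth through or replaces it with uniform noise", {
  set.seed(404)
  expect_equal(apply_perception_error(0.7, 0), 0.7)
  draws <- replicate(10000, apply_perception_error(0.7, 1))
  expect_true(all(draws >= 0 & draws <= 1))
  expect_equal(mean(draws), 0.5, tolerance = 0.04)
  # noise fabricates a value even where the true ratio is undefined
  fab <- replicate(50, apply_perception_error(NA_real_, 1))
  expect_true(all(!is.na(fab)))
})

test_that("the ostracism check honours its deterministic gates", {
  set.seed(405)
  # all gates pass deterministically
  expect_true(check_ostracism(1, 1, 1, 0, threshold = 0, e_p = 0, e_x = 0))
  # observer below the fusion threshold never checks
  expect_false(check_ostracism(0.5, 1, 1, 0, threshold = 0.6))
  # unfused parties cannot be involved
  expect_false(check_ostracism(0, 1, 1, 0))
  expect_false(check_ostracism(1, 0, 1, 0))
  # certain execution error always suppresses the response
  expect_false(check_ostracism(1, 1, 1, 0, e_x = 1))
  # non-hypocrite target is never ostracised
  expect_false(check_ostracism(1, 1, 0.5, 0.9))
})

test_that("partner selection draws in-group or globally and never the donor", {
  p_global <- tiny_params(s_policy = 0)
  fusion <- runif(12)
  set.seed(406)
  picks <- replicate(300, select_partner(3L, fusion, p_global))
  expect_false(any(picks == 3L))
  expect_true(all(picks %in% seq_len(12)))
  expect_gt(length(unique(picks)), 8)  # roughly uniform over the others

  # S = 1 with a single eligible in-group member picks it surely
  p_in <- tiny_params(s_policy = 1)
  f2 <- c(0.9, 0.95, rep(0.1, 10))
  expect_identical(replicate(20, select_partner(1L, f2, p_in)),
                   rep(2L, 20))
  # empty in-group falls back to a global draw
  f3 <- c(1.0, rep(0.2, 11))
  picks3 <- replicate(100, select_partner(1L, f3, p_in))
  expect_false(any(picks3 == 1L))
  expect_gt(length(unique(picks3)), 5)
  expect_error(select_partner(1L, 0.5, p_global), "two agents")
})

test_that("standing assessment rewards donation and penalises illegitimate defection", {
  p <- sim_params()
  don <- assess_interaction(TRUE, FALSE, 0.8, 2, 3, p)
  expect_identical(don$delta_personal, 1L)
  expect_identical(don$delta_group, 1L)
  expect_identical(don$counter, "pos")
  expect_equal(don$payoff_donor, -0.7)
  expect_equal(don$payoff_recipient, 1.0)

  # defection on an equally reputable partner is punished on both ledgers
  def <- assess_interaction(FALSE, FALSE, 0.8, 2, 2, p)
  expect_identical(def$delta_personal, -1L)
  expect_identical(def$delta_group, -1L)
  expect_identical(def$counter, "neg")
  expect_equal(def$payoff_donor, 0)

  # legitimate defection (less reputable partner) goes unpunished
  leg <- assess_interaction(FALSE, FALSE, 0.8, 2, 1.5, p)
  expect_identical(leg$delta_personal, 0L)
  expect_identical(leg$delta_group, 0L)
  expect_identical(leg$counter, "neu")

  # ostracism-forced defection: personal penalty only, group spared
  ost <- assess_interaction(FALSE, TRUE, 0.8, 2, 3, p)
  expect_identical(ost$delta_personal, -1L)
  expect_identical(ost$delta_group, 0L)
  expect_identical(ost$counter, "neu")

  # unfused donors never touch the group ledger or counters
  unf <- assess_interaction(FALSE, FALSE, 0, 2, 3, p)
  expect_identical(unf$delta_group, 0L)
  expect_identical(unf$counter, "none")
})

test_that("the extra donation cost is charged above the fusion threshold", {
  p <- sim_params(extra_cost = 0.105, threshold = 0.6)
  above <- assess_interaction(TRUE, FALSE, 0.7, 0, 0, p)
  below <- assess_interaction(TRUE, FALSE, 0.5, 0, 0, p)
  at <- assess_interaction(TRUE, FALSE, 0.6, 0, 0, p)
  expect_equal(above$payoff_donor, -0.805)
  expect_equal(below$payoff_donor, -0.7)
  expect_equal(at$payoff_donor, -0.805)  # the gate is fusion >= T
})

test_that("reputation clamping saturates at the caps", {
  expect_identical(clamp_rep(6L), 5L)
  expect_identical(clamp_rep(-7L), -5L)
  expect_identical(clamp_rep(c(-9L, 0L, 9L)), c(-5L, 0L, 5L))
})
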