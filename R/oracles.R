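# Brute-force oracles and deterministic micro-scenarios. These pin the
# encounter mechanics independently of the simulation engines: the
# exhaustive decision table enumerates every (rule vector, comparison
# class) pair, scripted traces replay hand-written encounter sequences
# with all stochastic gates forced, and the base-model reference is an
# independent implementation of the unfused model that the full engine
# must reduce to bit-exactly when fusion is pinned at zero.

#' Exhaustive donation-decision table
#'
#' Enumerates all 8 action-rule vectors crossed with the 3 comparison
#' classes and the resulting donate/defect outcome -- 24 rows. Used to
#' assert that [donation_decision()] agrees with direct enumeration on
#' every case.
#'
#' @return A data frame with columns `rule_s`, `rule_u`, `rule_d`,
#'   `comparison`, `donate`.
#' @examples
#' tab <- decision_rule_table()
#' nrow(tab) # 24
#' @export
decision_rule_table <- function() {
  rules <- expand.grid(rule_s = 0:1, rule_u = 0:1, rule_d = 0:1)
  classes <- c("similar", "upward", "downward")
  out <- do.call(rbind, lapply(classes, function(cl) {
    bit <- switch(cl,
                  similar = rules$rule_s,
                  upward = rules$rule_u,
                  downward = rules$rule_d)
    data.frame(rules, comparison = cl, donate = bit == 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Replay a scripted encounter sequence
#'
#' Replays a hand-written sequence of donation-game encounters with every
#' stochastic gate forced by the scenario itself: the donor and recipient
#' of each game are given, and interaction-stage ostracism is imposed (or
#' not) by the scenario rather than drawn. All deterministic mechanics --
#' reputation views, comparison classification, the donation decision
#' from the donor's action rules, standing assessment with the
#' ostracism exception, contribution counters and payoff transfers -- run
#' exactly as in a live simulation, so the resulting state trajectory can
#' be frozen as a golden record.
#'
#' @param pop Initial population list (see [init_population()]), typically
#'   hand-built for two or three agents.
#' @param scenario Data frame with one row per encounter: integer columns
#'   `donor` and `recipient`, and logical `ostracised` (force an
#'   interaction-stage ostracism of this encounter). An empty scenario
#'   returns the initial state unchanged.
#' @param params A [sim_params()] object (benefit, cost, threshold, delta).
#' @return A list with `steps`, a data frame recording every encounter's
#'   outcome and the post-encounter state of the donor and group
#'   (`donated`, `comparison`, `delta_personal`, `delta_group`,
#'   `r_donor`, `group_rep`, `n_pos`, `n_neu`, `n_neg`, `ctr_donor`,
#'   `payoff_donor`, `payoff_recipient`), and `pop`, the final population
#'   state.
#' @export
scripted_trace <- function(pop, scenario, params) {
  cols <- c("step", "donor", "recipient", "donated", "ostracised",
            "comparison", "delta_personal", "delta_group", "r_donor",
            "group_rep", "n_pos", "n_neu", "n_neg", "ctr_donor",
            "payoff_donor", "payoff_recipient")
  steps <- vector("list", nrow(scenario))
  if (nrow(scenario) > 0L) {
    for (k in seq_len(nrow(scenario))) {
      i <- scenario$donor[k]
      j <- scenario$recipient[k]
      forced <- isTRUE(scenario$ostracised[k])
      view_self <- perceived_reputation(pop$fusion[i], pop$fusion[i],
                                        pop$personal_rep[i], pop$group_rep)
      view_other <- perceived_reputation(pop$fusion[i], pop$fusion[j],
                                         pop$personal_rep[j], pop$group_rep)
      cls <- classify_comparison(view_self, view_other, params$delta)
      donated <- if (forced) FALSE else {
        donation_decision(pop$rule_s[i], pop$rule_u[i], pop$rule_d[i], cls)
      }
      out <- assess_interaction(donated, forced, pop$fusion[i],
                                view_self, view_other, params)
      pop$personal_rep[i] <- clamp_rep(pop$personal_rep[i] +
                                         out$delta_personal)
      if (out$delta_group != 0L) {
        pop$group_rep <- clamp_rep(pop$group_rep + out$delta_group)
      }
      if (out$counter == "pos") pop$n_pos[i] <- pop$n_pos[i] + 1L
      if (out$counter == "neu") pop$n_neu[i] <- pop$n_neu[i] + 1L
      if (out$counter == "neg") pop$n_neg[i] <- pop$n_neg[i] + 1L
      pop$payoff[i] <- pop$payoff[i] + out$payoff_donor
      pop$payoff[j] <- pop$payoff[j] + out$payoff_recipient
      steps[[k]] <- data.frame(
        step = k, donor = i, recipient = j, donated = donated,
        ostracised = forced, comparison = cls,
        delta_personal = out$delta_personal,
        delta_group = out$delta_group,
        r_donor = pop$personal_rep[i], group_rep = pop$group_rep,
        n_pos = pop$n_pos[i], n_neu = pop$n_neu[i], n_neg = pop$n_neg[i],
        ctr_donor = contribution_ratio(pop$n_pos[i], pop$n_neu[i],
                                       pop$n_neg[i]),
        payoff_donor = pop$payoff[i], payoff_recipient = pop$payoff[j],
        stringsAsFactors = FALSE
      )
    }
  }
  steps_df <- if (length(steps)) do.call(rbind, steps) else {
    as.data.frame(stats::setNames(replicate(length(cols), logical(0),
                                            simplify = FALSE), cols))
  }
  list(steps = steps_df, pop = pop)
}

#' Reference implementation of the unfused base model
#'
#' An independent pure-R implementation of indirect reciprocity with only
#' isolated personal reputations: no fusion, no group reputation, no
#' contribution counters, no ostracism machinery. It consumes the RNG
#' stream in the same documented order as the full engines, so a full-model
#' run with every fusion level pinned at zero (`mutate_fusion = FALSE`)
#' must reproduce it bit-exactly from the same seed -- the reduction
#' property of the model. In this regime cooperation is expected to emerge
#' with the dominant action rule (1, 1, 0): donate on similarity and
#' upward comparison, defect downward.
#'
#' @param params A [sim_params()] object with `mutate_fusion = FALSE`.
#' @return A list shaped like a [run_model()] result: `metrics` (with
#'   `avg_cooperation` and `avg_fusion`, the latter always 0),
#'   `trajectory` data frame and `final_pop`, where `final_pop$fusion` is
#'   all zero and `final_pop$group_rep` is 0, untouched by construction.
#' @export
base_model_reference <- function(params) {
  stopifnot(inherits(params, "sim_params"), !params$mutate_fusion)
  n <- params$n_agents
  set.seed(params$seed)
  rule_s <- as.integer(stats::runif(n) < 0.5)
  rule_u <- as.integer(stats::runif(n) < 0.5)
  rule_d <- as.integer(stats::runif(n) < 0.5)
  rep_ <- integer(n)
  payoff <- numeric(n)
  s_fixed <- if (identical(params$s_policy, "fusion")) 0 else params$s_policy
  cost <- params$cost +
    if (0 >= params$threshold) params$extra_cost else 0
  M <- params$generations
  cum_don <- 0; cum_games <- 0
  traj <- data.frame(generation = seq_len(M), avg_coop = NA_real_,
                     avg_fusion = 0, mean_payoff = NA_real_,
                     group_rep = 0L, donations = NA_integer_)
  for (gen in seq_len(M)) {
    donations <- 0L
    for (g in seq_len(params$games_per_gen)) {
      i <- 1L + floor(stats::runif(1) * n)
      # in-group gate: with all fusion equal the in-group is everyone,
      # so the partner formula is the same either way; the gate draw is
      # still consumed to mirror the full engine's stream
      stats::runif(1)
      t <- 1L + floor(stats::runif(1) * (n - 1L))
      j <- if (t >= i) t + 1L else t
      ri <- rep_[i]; rj <- rep_[j]
      bit <- if (rj > ri + params$delta) rule_u[i]
             else if (rj < ri - params$delta) rule_d[i]
             else rule_s[i]
      if (bit == 1L) {
        rep_[i] <- min(5L, rep_[i] + 1L)
        payoff[i] <- payoff[i] - cost
        payoff[j] <- payoff[j] + params$benefit
        donations <- donations + 1L
      } else {
        if (rj >= ri) rep_[i] <- max(-5L, rep_[i] - 1L)
        payoff[j] <- payoff[j] + 0
      }
    }
    cum_don <- cum_don + donations
    cum_games <- cum_games + params$games_per_gen
    traj$avg_coop[gen] <- if (cum_games > 0) cum_don / cum_games else NA
    traj$mean_payoff[gen] <- mean(payoff)
    traj$donations[gen] <- donations
    # roulette selection over shifted payoffs, then rule-bit mutation
    w <- payoff - min(0, min(payoff))
    new_s <- integer(n); new_u <- integer(n); new_d <- integer(n)
    for (i in seq_len(n)) {
      parent <- roulette_draw(w, seq_len(n))
      s <- rule_s[parent]; u <- rule_u[parent]; d <- rule_d[parent]
      if (stats::runif(1) < params$mutation_rate) s <- 1L - s
      if (stats::runif(1) < params$mutation_rate) u <- 1L - u
      if (stats::runif(1) < params$mutation_rate) d <- 1L - d
      new_s[i] <- s; new_u[i] <- u; new_d[i] <- d
    }
    rule_s <- new_s; rule_u <- new_u; rule_d <- new_d
    rep_ <- integer(n); payoff <- numeric(n)
  }
  metrics <- list(cum_donations = cum_don, cum_games = cum_games,
                  cum_fusion_sum = 0, gen_count = M,
                  avg_cooperation = cum_don / cum_games, avg_fusion = 0)
  list(metrics = metrics, trajectory = traj,
       final_pop = list(fusion = numeric(n), rule_s = rule_s,
                        rule_u = rule_u, rule_d = rule_d,
                        personal_rep = rep_, payoff = payoff,
                        n_pos = integer(n), n_neu = integer(n),
                        n_neg = integer(n), group_rep = 0L))
}
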