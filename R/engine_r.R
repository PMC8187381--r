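# Pure-R simulation engine. Mirrors the compiled engine draw for draw:
# every uniform variate is consumed in the same order, so that for a given
# seed the two engines produce bit-identical trajectories. Used as a
# cross-check oracle at small problem sizes; run_model() defaults to the
# compiled engine.

#' Run one generation (pure-R engine)
#'
#' Executes the generation's donation games, accumulates metrics, then
#' applies selection, reproduction, mutation and state reset. Exposed for
#' testing and for scripted micro-scenarios; [run_model()] drives whole
#' runs.
#'
#' Per game the draw order is: donor index; in-group gate; partner index;
#' (types 1 and 3 only) the hypocrisy-check draws of [check_ostracism()].
#' The donation decision, payoff transfer and standing assessment are
#' deterministic given those draws.
#'
#' @param pop Population list (see [init_population()]).
#' @param params A [sim_params()] object.
#' @param metrics A metrics list as made by [new_metrics()].
#' @return List with elements `pop` (next generation), `metrics`
#'   (updated), `donations` (count this generation), and `parent_pop`
#'   (the population at the end of its games, before replacement).
#' @export
run_generation <- function(pop, params, metrics) {
  n <- params$n_agents
  interaction_ostracism <- params$ostracism_type %in% c(1L, 3L)
  donations <- 0L
  for (g in seq_len(params$games_per_gen)) {
    i <- 1L + floor(stats::runif(1) * n)
    j <- select_partner(i, pop$fusion, params)
    view_self <- perceived_reputation(pop$fusion[i], pop$fusion[i],
                                      pop$personal_rep[i], pop$group_rep)
    view_other <- perceived_reputation(pop$fusion[i], pop$fusion[j],
                                       pop$personal_rep[j], pop$group_rep)
    ostracised <- FALSE
    if (interaction_ostracism) {
      ctr_i <- contribution_ratio(pop$n_pos[i], pop$n_neu[i], pop$n_neg[i])
      ctr_j <- contribution_ratio(pop$n_pos[j], pop$n_neu[j], pop$n_neg[j])
      ostracised <- check_ostracism(pop$fusion[i], pop$fusion[j],
                                    ctr_i, ctr_j, params$threshold,
                                    params$err_perception,
                                    params$err_execution)
    }
    donated <- if (ostracised) {
      FALSE
    } else {
      cls <- classify_comparison(view_self, view_other, params$delta)
      donation_decision(pop$rule_s[i], pop$rule_u[i], pop$rule_d[i], cls)
    }
    out <- assess_interaction(donated, ostracised, pop$fusion[i],
                              view_self, view_other, params)
    pop$personal_rep[i] <- clamp_rep(pop$personal_rep[i] + out$delta_personal)
    if (out$delta_group != 0L) {
      pop$group_rep <- clamp_rep(pop$group_rep + out$delta_group)
    }
    if (out$counter == "pos") pop$n_pos[i] <- pop$n_pos[i] + 1L
    if (out$counter == "neu") pop$n_neu[i] <- pop$n_neu[i] + 1L
    if (out$counter == "neg") pop$n_neg[i] <- pop$n_neg[i] + 1L
    pop$payoff[i] <- pop$payoff[i] + out$payoff_donor
    pop$payoff[j] <- pop$payoff[j] + out$payoff_recipient
    if (donated) donations <- donations + 1L
  }
  metrics$cum_donations <- metrics$cum_donations + donations
  metrics$cum_games <- metrics$cum_games + params$games_per_gen
  metrics$cum_fusion_sum <- metrics$cum_fusion_sum + sum(pop$fusion)
  metrics$gen_count <- metrics$gen_count + 1L
  parent <- pop
  pop <- reproduce_population(pop, params)
  list(pop = pop, metrics = metrics, donations = donations,
       parent_pop = parent)
}

#' Fresh metrics accumulator
#'
#' Running totals from which the headline metrics derive: average
#' cooperation is cumulative donations over cumulative games; average
#' fusion is the cumulative sum of fusion levels over generation-agent
#' pairs.
#'
#' @return A list with zeroed `cum_donations`, `cum_games`,
#'   `cum_fusion_sum`, `gen_count`.
#' @export
new_metrics <- function() {
  list(cum_donations = 0, cum_games = 0, cum_fusion_sum = 0, gen_count = 0L)
}

# Full run with the pure-R engine. Assumes the RNG is already seeded and
# the initial population already drawn.
run_sim_r <- function(pop, params) {
  metrics <- new_metrics()
  M <- params$generations
  n <- params$n_agents
  traj <- list(avg_coop = numeric(M), avg_fusion = numeric(M),
               mean_payoff = numeric(M), group_rep = integer(M),
               donations = integer(M))
  for (gen in seq_len(M)) {
    step <- run_generation(pop, params, metrics)
    metrics <- step$metrics
    traj$avg_coop[gen] <- if (metrics$cum_games > 0) {
      metrics$cum_donations / metrics$cum_games
    } else NA_real_
    traj$avg_fusion[gen] <- metrics$cum_fusion_sum / (metrics$gen_count * n)
    traj$mean_payoff[gen] <- mean(step$parent_pop$payoff)
    traj$group_rep[gen] <- step$parent_pop$group_rep
    traj$donations[gen] <- step$donations
    pop <- step$pop
  }
  list(metrics = metrics, trajectory = traj, final_pop = pop)
}
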