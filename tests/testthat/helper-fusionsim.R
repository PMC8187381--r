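# Hand-built populations for micro-scenarios. All per-agent vectors are
# recycled to the length of `fusion`.
make_pop <- function(fusion, rule_s = 1L, rule_u = 1L, rule_d = 0L,
                     personal_rep = 0L, payoff = 0, n_pos = 0L,
                     n_neu = 0L, n_neg = 0L, group_rep = 0L) {
  n <- length(fusion)
  list(
    fusion = as.numeric(fusion),
    rule_s = rep_len(as.integer(rule_s), n),
    rule_u = rep_len(as.integer(rule_u), n),
    rule_d = rep_len(as.integer(rule_d), n),
    personal_rep = rep_len(as.integer(personal_rep), n),
    payoff = rep_len(as.numeric(payoff), n),
    n_pos = rep_len(as.integer(n_pos), n),
    n_neu = rep_len(as.integer(n_neu), n),
    n_neg = rep_len(as.integer(n_neg), n),
    group_rep = as.integer(group_rep)
  )
}

# Small parameter set for fast unit runs.
tiny_params <- function(...) {
  args <- utils::modifyList(
    list(n_agents = 12L, games_per_gen = 60L, generations = 5L,
         seed = 99L),
    list(...))
  do.call(sim_params, args)
}

# Desk-scale experiment used by the acceptance criteria: N = 100,
# m = 5000, M = 2000 generations, 3 seeds, seed-averaged.
desk_metrics <- function(first_seed = 1L, ...) {
  p <- sim_params(generations = 2000L, seed = as.integer(first_seed), ...)
  ex <- run_experiment(p, n_seeds = 3L, record = FALSE)
  c(coop = ex$avg_cooperation, fusion = ex$avg_fusion)
}
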