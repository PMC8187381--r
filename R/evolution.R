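#' Selection weights from payoffs
#'
#' Roulette-wheel selection uses payoff as fitness. Payoffs can be
#' negative (an agent can pay costs without receiving donations), so
#' weights are payoffs shifted by the most negative payoff in the
#' population (no shift when all are non-negative). If every shifted
#' payoff is zero, selection is uniform.
#'
#' @param payoffs Numeric vector of per-agent payoffs.
#' @return Non-negative weights summing to 1.
#' @examples
#' fitness_weights(c(2, 1, 1))  # 0.50 0.25 0.25
#' fitness_weights(c(-1, 0, 3)) # 0.0 0.2 0.8
#' @export
fitness_weights <- function(payoffs) {
  stopifnot(length(payoffs) >= 1L)
  w <- payoffs - min(0, min(payoffs))
  s <- sum(w)
  if (s <= 0) rep(1 / length(w), length(w)) else w / s
}

# One roulette draw over candidate indices, walking the unnormalised
# shifted weights in index order. Consumes exactly one uniform draw.
# The C++ engine performs the identical walk.
roulette_draw <- function(weights, candidates) {
  w <- weights[candidates]
  total <- sum(w)
  u <- stats::runif(1)
  if (total <= 0) {
    return(candidates[1L + floor(u * length(candidates))])
  }
  r <- u * total
  acc <- 0
  for (k in seq_along(candidates)) {
    acc <- acc + w[k]
    if (r < acc) return(candidates[k])
  }
  candidates[length(candidates)]
}

#' Mutate heritable elements of offspring
#'
#' Each of the three action-rule bits flips independently with probability
#' `mu`; the fusion level is independently resampled from Uniform(0, 1)
#' with probability `mu` (mutation replaces rather than perturbs, matching
#' the uniform initialisation). Draw order per agent: s gate, u gate, d
#' gate, fusion gate, then the replacement value only if the fusion gate
#' fires. With `mutate_fusion = FALSE` the fusion gate is skipped entirely
#' and no draws are consumed for it.
#'
#' @param rule_s,rule_u,rule_d Integer rule bits of one offspring.
#' @param fusion Fusion level of one offspring.
#' @param mu Mutation rate.
#' @param mutate_fusion Logical; mutate the fusion level too?
#' @return List with the four (possibly mutated) heritable elements.
#' @export
mutate_agent <- function(rule_s, rule_u, rule_d, fusion, mu,
                         mutate_fusion = TRUE) {
  if (stats::runif(1) < mu) rule_s <- 1L - rule_s
  if (stats::runif(1) < mu) rule_u <- 1L - rule_u
  if (stats::runif(1) < mu) rule_d <- 1L - rule_d
  if (mutate_fusion && stats::runif(1) < mu) fusion <- stats::runif(1)
  list(rule_s = rule_s, rule_u = rule_u, rule_d = rule_d, fusion = fusion)
}

#' End-of-generation selection, reproduction and reset
#'
#' Each slot of the next generation independently selects a parent from
#' the current population by roulette-wheel over shifted payoffs
#' ([fitness_weights()]); the candidate pool includes the reproducing
#' agent itself. Under reproduction-stage ostracism (types 2 and 3) the
#' reproducing agent first excludes every candidate it perceives as a
#' hypocrite, checking each candidate (never itself) with an independent
#' fusion-gated draw and independent perception/execution error draws; if
#' its exclusions empty the pool it reproduces from the full population.
#' The offspring copies the parent's action rules and fusion level and is
#' then mutated. All payoffs, reputations (personal and group) and
#' contribution counters reset to zero.
#'
#' Draw order per slot, matching the compiled engine: the per-candidate
#' hypocrisy checks in increasing candidate index (skipping the slot
#' itself), one selection draw, then the mutation draws.
#'
#' @param pop Population list (see [init_population()]).
#' @param params A [sim_params()] object.
#' @return The next-generation population list, with `group_rep = 0`.
#' @export
reproduce_population <- function(pop, params) {
  n <- params$n_agents
  w <- pop$payoff - min(0, min(pop$payoff))
  ctr <- contribution_ratio(pop$n_pos, pop$n_neu, pop$n_neg)
  child <- list(
    fusion = numeric(n), rule_s = integer(n), rule_u = integer(n),
    rule_d = integer(n),
    personal_rep = integer(n), payoff = numeric(n),
    n_pos = integer(n), n_neu = integer(n), n_neg = integer(n),
    group_rep = 0L
  )
  repro_ostracism <- params$ostracism_type %in% c(2L, 3L)
  for (i in seq_len(n)) {
    candidates <- seq_len(n)
    if (repro_ostracism && pop$fusion[i] >= params$threshold &&
        pop$fusion[i] > 0) {
      keep <- rep(TRUE, n)
      for (j in seq_len(n)) {
        if (j == i) next
        if (check_ostracism(pop$fusion[i], pop$fusion[j], ctr[i], ctr[j],
                            params$threshold, params$err_perception,
                            params$err_execution)) {
          keep[j] <- FALSE
        }
      }
      if (any(keep)) candidates <- which(keep)
    }
    parent <- roulette_draw(w, candidates)
    mut <- mutate_agent(pop$rule_s[parent], pop$rule_u[parent],
                        pop$rule_d[parent], pop$fusion[parent],
                        params$mutation_rate, params$mutate_fusion)
    child$fusion[i] <- mut$fusion
    child$rule_s[i] <- mut$rule_s
    child$rule_u[i] <- mut$rule_u
    child$rule_d[i] <- mut$rule_d
  }
  child
}

#' Initial population
#'
#' Action-rule bits are independent Bernoulli(1/2); fusion levels are
#' Uniform(0, 1) (or all zero with `mutate_fusion = FALSE`, the base-model
#' reduction). Reputations, payoffs and counters start at zero. Draw
#' order: the three rule bits for all agents (s, u, d in turn, each a
#' block of `n` draws), then all fusion levels.
#'
#' @param params A [sim_params()] object.
#' @return A population list with per-agent vectors `fusion`, `rule_s`,
#'   `rule_u`, `rule_d`, `personal_rep`, `payoff`, `n_pos`, `n_neu`,
#'   `n_neg`, and the scalar shared `group_rep`.
#' @export
init_population <- function(params) {
  n <- params$n_agents
  pop <- list(
    rule_s = as.integer(stats::runif(n) < 0.5),
    rule_u = as.integer(stats::runif(n) < 0.5),
    rule_d = as.integer(stats::runif(n) < 0.5),
    fusion = if (params$mutate_fusion) stats::runif(n) else numeric(n),
    personal_rep = integer(n), payoff = numeric(n),
    n_pos = integer(n), n_neu = integer(n), n_neg = integer(n),
    group_rep = 0L
  )
  pop
}
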