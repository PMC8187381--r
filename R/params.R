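#' Simulation parameters
#'
#' Construct and validate the full parameter set for a simulation run.
#' Defaults follow the study conditions of the model: a population of
#' `N = 100` agents, `m = 5000` donation games per generation, benefit
#' `b = 1` and cost `c = 0.7`, mutation at 1% per heritable element, and
#' no perception or execution errors.
#'
#' @param n_agents Population size `N`.
#' @param games_per_gen Donation games per generation `m`.
#' @param generations Number of generations `M`. The long-run scale used for
#'   headline results is 50,000; the package's "desk" preset (see
#'   [preset_params()]) uses 2,000, which preserves the qualitative regimes.
#' @param benefit Benefit `b` received by the recipient of a donation.
#' @param cost Cost `c` paid by the donor; requires `benefit > cost > 0`.
#' @param extra_cost Additional donation cost `c_T >= 0` charged to agents
#'   with fusion at or above `threshold`. Used in the differential-cost
#'   experiments; 0 by default.
#' @param threshold Minimum fusion level `T` (in `[0, 1)`) an agent must
#'   reach before it may ostracise; also gates `extra_cost`.
#' @param delta Similarity band for social comparison of reputations.
#'   The model fixes `delta = 0`: similarity means exact equality of the
#'   two (real-valued) reputation views.
#' @param mutation_rate Per-element mutation probability `mu`.
#' @param ostracism_type One of 0 (none), 1 (interaction stage), 2
#'   (reproduction stage) or 3 (both).
#' @param s_policy In-group mixing policy. Either a fixed probability in
#'   `[0, 1]` that a donor draws its partner from its in-group (agents at
#'   least as fused as itself), or the string `"fusion"` meaning the
#'   probability equals the donor's own fusion level. `0` means global
#'   uniform mixing.
#' @param err_perception Perception error rate `e_p`: probability that a
#'   perceived contribution ratio is replaced by a Uniform(0,1) draw.
#' @param err_execution Execution error rate `e_x`: probability that an
#'   ostracism that should happen is not performed.
#' @param mutate_fusion Logical; if `FALSE`, fusion levels are never mutated
#'   (and no RNG draws are consumed for fusion mutation). Used by the
#'   base-model reduction, where fusion is pinned at zero.
#' @param seed Integer RNG seed for [run_model()].
#'
#' @return An object of class `sim_params`: a validated named list.
#' @seealso [preset_params()], [run_model()], [run_experiment()]
#' @examples
#' p <- sim_params(generations = 10, games_per_gen = 100, seed = 1)
#' p
#' @export
sim_params <- function(n_agents = 100L,
                       games_per_gen = 5000L,
                       generations = 50000L,
                       benefit = 1.0,
                       cost = 0.7,
                       extra_cost = 0.0,
                       threshold = 0.0,
                       delta = 0L,
                       mutation_rate = 0.01,
                       ostracism_type = 0L,
                       s_policy = 0,
                       err_perception = 0.0,
                       err_execution = 0.0,
                       mutate_fusion = TRUE,
                       seed = 1L) {
  p <- list(
    n_agents = as.integer(n_agents),
    games_per_gen = as.integer(games_per_gen),
    generations = as.integer(generations),
    benefit = as.numeric(benefit),
    cost = as.numeric(cost),
    extra_cost = as.numeric(extra_cost),
    threshold = as.numeric(threshold),
    delta = as.numeric(delta),
    mutation_rate = as.numeric(mutation_rate),
    ostracism_type = as.integer(ostracism_type),
    s_policy = if (identical(s_policy, "fusion")) "fusion" else as.numeric(s_policy),
    err_perception = as.numeric(err_perception),
    err_execution = as.numeric(err_execution),
    mutate_fusion = isTRUE(mutate_fusion),
    seed = as.integer(seed)
  )
  validate_sim_params(structure(p, class = "sim_params"))
}

validate_sim_params <- function(p) {
  stopifnot(
    p$n_agents >= 2L,
    p$games_per_gen >= 0L,
    p$generations >= 1L,
    p$benefit > p$cost, p$cost > 0,
    p$extra_cost >= 0,
    p$threshold >= 0, p$threshold < 1,
    p$delta >= 0,
    p$mutation_rate >= 0, p$mutation_rate <= 1,
    p$ostracism_type %in% 0:3,
    p$err_perception >= 0, p$err_perception <= 1,
    p$err_execution >= 0, p$err_execution <= 1
  )
  if (!identical(p$s_policy, "fusion")) {
    stopifnot(p$s_policy >= 0, p$s_policy <= 1)
  }
  p
}

#' Preset parameter sets
#'
#' Two problem scales for experiments. `"paper"` is the full long-run scale
#' (50,000 generations, 5 seeds per condition); `"desk"` is a scaled-down
#' configuration (2,000 generations, 3 seeds) that runs in minutes per
#' condition while preserving the qualitative regimes of the model.
#'
#' @param scale `"desk"` or `"paper"`.
#' @param ... Overrides passed on to [sim_params()].
#' @return A list with elements `params` (a `sim_params` object) and
#'   `n_seeds` (the number of independent replicate runs per condition).
#' @examples
#' preset_params("desk", ostracism_type = 3)$n_seeds
#' @export
preset_params <- function(scale = c("desk", "paper"), ...) {
  scale <- match.arg(scale)
  if (scale == "paper") {
    list(params = sim_params(generations = 50000L, ...), n_seeds = 5L)
  } else {
    list(params = sim_params(generations = 2000L, ...), n_seeds = 3L)
  }
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters\n")
  cat(sprintf("  population N = %d, games/generation m = %d, generations M = %d\n",
              x$n_agents, x$games_per_gen, x$generations))
  cat(sprintf("  benefit b = %g, cost c = %g, extra cost c_T = %g (fusion >= T = %g)\n",
              x$benefit, x$cost, x$extra_cost, x$threshold))
  cat(sprintf("  ostracism type %d; in-group mixing S = %s; delta = %g\n",
              x$ostracism_type,
              if (identical(x$s_policy, "fusion")) "f_i" else format(x$s_policy),
              x$delta))
  cat(sprintf("  errors: perception e_p = %g, execution e_x = %g\n",
              x$err_perception, x$err_execution))
  cat(sprintf("  mutation mu = %g (%s), seed = %d\n",
              x$mutation_rate,
              if (x$mutate_fusion) "rules + fusion" else "rules only",
              x$seed))
  invisible(x)
}

# s_policy encoded for the C++ engine: -1 = "fusion", otherwise the fixed
# probability.
s_policy_code <- function(p) {
  if (identical(p$s_policy, "fusion")) -1.0 else as.numeric(p$s_policy)
}

# Effective in-group interaction probability for a donor with fusion f.
s_prob <- function(p, f) {
  if (identical(p$s_policy, "fusion")) f else p$s_policy
}

# Small FNV-1a hash of a parameter list, for provenance columns in sweep
# tables (rerunning a sweep with the same config reproduces the same hash).
config_hash <- function(p) {
  s <- paste(deparse(unclass(p), control = "all"), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
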