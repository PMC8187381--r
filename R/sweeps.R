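# Config-driven parameter sweeps. Each sweep is a pure function of its
# arguments: one row per (condition, seed summary), with full provenance
# columns (every parameter plus a config hash) so any row can be
# regenerated from the table alone.

sweep_row <- function(params, n_seeds, engine, extra = list()) {
  ex <- run_experiment(params, n_seeds = n_seeds, engine = engine,
                       record = FALSE)
  base <- data.frame(
    ostracism_type = params$ostracism_type,
    s_policy = if (identical(params$s_policy, "fusion")) "fusion"
               else format(params$s_policy),
    threshold = params$threshold,
    err_perception = params$err_perception,
    err_execution = params$err_execution,
    extra_cost = params$extra_cost,
    n_agents = params$n_agents,
    games_per_gen = params$games_per_gen,
    generations = params$generations,
    benefit = params$benefit,
    cost = params$cost,
    mutation_rate = params$mutation_rate,
    n_seeds = length(ex$seeds),
    first_seed = ex$seeds[1],
    avg_cooperation = ex$avg_cooperation,
    avg_fusion = ex$avg_fusion,
    sd_cooperation = stats::sd(ex$per_seed$avg_cooperation),
    sd_fusion = stats::sd(ex$per_seed$avg_fusion),
    config_hash = config_hash(params),
    stringsAsFactors = FALSE
  )
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}

#' Sweep over in-group mixing and ostracism type
#'
#' Crosses ostracism types with in-group mixing settings `S_i` (fixed
#' values and/or the `"fusion"` policy `S_i = f_i`) and reports the final
#' cumulative average cooperation and average fusion, seed-averaged.
#'
#' @param base_params A [sim_params()] object giving the shared settings;
#'   `ostracism_type` and `s_policy` are overridden by the grids.
#' @param ostracism_types Integer vector from `{0, 1, 2, 3}`.
#' @param s_values List or vector of mixing settings: numbers in `[0, 1]`
#'   and/or the string `"fusion"`.
#' @param n_seeds Seeds per condition (replicates are consecutive from
#'   `base_params$seed`).
#' @param engine Passed to [run_model()].
#' @return A data frame, one row per (type, S) condition, with metric and
#'   provenance columns.
#' @export
sweep_s_policy <- function(base_params, ostracism_types = 0:3,
                           s_values = list(0, 0.1, 0.5, 0.9, "fusion"),
                           n_seeds = 3L, engine = "cpp") {
  if (length(s_values) == 0L || length(ostracism_types) == 0L) {
    return(data.frame())
  }
  rows <- list()
  for (ot in ostracism_types) {
    for (s in s_values) {
      p <- base_params
      p$ostracism_type <- as.integer(ot)
      p$s_policy <- if (identical(s, "fusion")) "fusion" else as.numeric(s)
      rows[[length(rows) + 1L]] <- sweep_row(p, n_seeds, engine)
    }
  }
  do.call(rbind, rows)
}

#' Sweep over the ostracism fusion threshold
#'
#' Varies the minimum fusion level `T` an agent must reach before it may
#' ostracise, for the ostracism types that act on hypocrisy. High `T`
#' probes whether a highly fused subgroup suffices to invoke
#' population-wide fusion.
#'
#' @param base_params Shared settings; `threshold` and `ostracism_type`
#'   are overridden. The in-group policy conventionally stays
#'   `s_policy = "fusion"` for this sweep.
#' @param thresholds Numeric vector of `T` values in `[0, 1)`.
#' @param ostracism_types Integer vector from `{1, 2, 3}`.
#' @param n_seeds,engine See [sweep_s_policy()].
#' @return A data frame, one row per (type, T) condition.
#' @export
sweep_threshold <- function(base_params,
                            thresholds = c(0, 0.2, 0.4, 0.6, 0.8),
                            ostracism_types = c(1L, 2L, 3L),
                            n_seeds = 3L, engine = "cpp") {
  rows <- list()
  for (ot in ostracism_types) {
    for (T_ in thresholds) {
      p <- base_params
      p$ostracism_type <- as.integer(ot)
      p$threshold <- as.numeric(T_)
      rows[[length(rows) + 1L]] <- sweep_row(p, n_seeds, engine)
    }
  }
  do.call(rbind, rows)
}

#' Sweep over perception and execution error rates
#'
#' Varies the execution error rate `e_x` (failing to ostracise a
#' perceived hypocrite) and, separately, the perception error rate `e_p`
#' (the perceived contribution ratio replaced by a Uniform(0,1) draw).
#' The two grids are swept one at a time, the other error held at zero,
#' matching how error robustness is reported.
#'
#' @param base_params Shared settings; `err_execution`/`err_perception`
#'   and `ostracism_type` are overridden.
#' @param e_x_values,e_p_values Numeric grids in `[0, 1]`.
#' @param ostracism_types Integer vector from `{1, 2, 3}`.
#' @param n_seeds,engine See [sweep_s_policy()].
#' @return A data frame with an extra `error_kind` column (`"execution"`
#'   or `"perception"`), one row per (type, kind, rate) condition.
#' @export
sweep_errors <- function(base_params,
                         e_x_values = c(0, 0.1, 0.2, 0.3, 0.4),
                         e_p_values = c(0, 0.1, 0.2, 0.3, 0.4),
                         ostracism_types = c(1L, 2L, 3L),
                         n_seeds = 3L, engine = "cpp") {
  rows <- list()
  for (ot in ostracism_types) {
    for (ex_ in e_x_values) {
      p <- base_params
      p$ostracism_type <- as.integer(ot)
      p$err_execution <- as.numeric(ex_)
      p$err_perception <- 0
      rows[[length(rows) + 1L]] <-
        sweep_row(p, n_seeds, engine,
                  list(error_kind = "execution", error_rate = ex_))
    }
    for (ep_ in e_p_values) {
      p <- base_params
      p$ostracism_type <- as.integer(ot)
      p$err_perception <- as.numeric(ep_)
      p$err_execution <- 0
      rows[[length(rows) + 1L]] <-
        sweep_row(p, n_seeds, engine,
                  list(error_kind = "perception", error_rate = ep_))
    }
  }
  do.call(rbind, rows)
}

#' Sweep over the differential donation cost
#'
#' Agents with fusion at or above the threshold `T` pay `c + c_T` per
#' donation instead of `c`, a marginal overhead for would-be ostracisers.
#' `c_T` is specified as a fraction of `c` and crossed with a grid of
#' thresholds under type-3 ostracism.
#'
#' @param base_params Shared settings; `extra_cost`, `threshold` and
#'   `ostracism_type` are overridden.
#' @param ct_fractions `c_T` as fractions of `c` (e.g. 0.05 to 0.30).
#' @param thresholds Grid of `T` values.
#' @param n_seeds,engine See [sweep_s_policy()].
#' @return A data frame with an extra `ct_fraction` column, one row per
#'   (fraction, T) condition.
#' @export
sweep_cost <- function(base_params,
                       ct_fractions = c(0, 0.05, 0.15, 0.30),
                       thresholds = c(0, 0.2, 0.4, 0.6, 0.8),
                       n_seeds = 3L, engine = "cpp") {
  rows <- list()
  for (fr in ct_fractions) {
    for (T_ in thresholds) {
      p <- base_params
      p$ostracism_type <- 3L
      p$extra_cost <- as.numeric(fr) * p$cost
      p$threshold <- as.numeric(T_)
      rows[[length(rows) + 1L]] <-
        sweep_row(p, n_seeds, engine, list(ct_fraction = fr))
    }
  }
  do.call(rbind, rows)
}
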