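#' Run one simulation
#'
#' Runs the full generational loop: each generation plays
#' `games_per_gen` donation games (donor draw, partner selection with
#' in-group mixing, optional interaction-stage ostracism, donation
#' decision, payoff transfer, standing assessment), then applies
#' roulette-wheel selection (with optional reproduction-stage ostracism),
#' mutation and state reset. Metrics are cumulative: average cooperation
#' is total donations over total games played so far; average fusion is
#' the mean fusion level over all generation-agent pairs so far, with each
#' generation's fusion recorded at the end of its games, before
#' replacement.
#'
#' The compiled engine and the pure-R engine consume the RNG stream in an
#' identical, documented order, so both produce bit-identical runs from
#' the same seed; the R engine exists as a cross-check and is only
#' practical at small problem sizes.
#'
#' @param params A [sim_params()] object.
#' @param engine `"cpp"` (default) or `"r"`.
#' @param init Optional initial population list (as from
#'   [init_population()]); when supplied, no initialisation draws are
#'   consumed. Useful for monomorphic or scripted starting conditions.
#' @param record Record per-generation trajectories? (`TRUE` by default;
#'   turning it off saves memory on very long runs.)
#' @return An object of class `fusion_sim` with components `params`,
#'   `engine`, `metrics` (cumulative accumulator plus the derived
#'   `avg_cooperation` and `avg_fusion`), `trajectory` (a data frame with
#'   one row per generation: `generation`, `avg_coop`, `avg_fusion`,
#'   `mean_payoff`, `group_rep`, `donations`), and `final_pop`.
#' @examples
#' p <- sim_params(n_agents = 20, games_per_gen = 200, generations = 20,
#'                 ostracism_type = 3, s_policy = "fusion", seed = 42)
#' fit <- run_model(p)
#' fit
#' @export
run_model <- function(params, engine = c("cpp", "r"), init = NULL,
                      record = TRUE) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  pop <- if (is.null(init)) init_population(params) else init
  if (engine == "cpp") {
    plist <- unclass(params)
    plist$s_policy_code <- s_policy_code(params)
    out <- cpp_run_sim(plist, pop, record)
    metrics <- out$metrics
    traj <- out$trajectory
    final_pop <- out$final_pop
  } else {
    out <- run_sim_r(pop, params)
    metrics <- out$metrics
    traj <- if (record) out$trajectory else NULL
    final_pop <- out$final_pop
  }
  metrics$avg_cooperation <- if (metrics$cum_games > 0) {
    metrics$cum_donations / metrics$cum_games
  } else NA_real_
  metrics$avg_fusion <-
    metrics$cum_fusion_sum / (metrics$gen_count * params$n_agents)
  traj_df <- NULL
  if (record && !is.null(traj) && length(traj) > 0) {
    traj_df <- data.frame(
      generation = seq_len(params$generations),
      avg_coop = traj$avg_coop,
      avg_fusion = traj$avg_fusion,
      mean_payoff = traj$mean_payoff,
      group_rep = traj$group_rep,
      donations = traj$donations
    )
  }
  structure(
    list(params = params, engine = engine, metrics = metrics,
         trajectory = traj_df, final_pop = final_pop),
    class = "fusion_sim"
  )
}

#' @export
print.fusion_sim <- function(x, ...) {
  cat("Identity-fusion / indirect-reciprocity simulation\n")
  cat(sprintf("  N = %d agents, m = %d games/gen, M = %d generations, seed %d\n",
              x$params$n_agents, x$params$games_per_gen,
              x$params$generations, x$params$seed))
  cat(sprintf("  ostracism type %d, S = %s, T = %g, e_p = %g, e_x = %g\n",
              x$params$ostracism_type,
              if (identical(x$params$s_policy, "fusion")) "f_i"
              else format(x$params$s_policy),
              x$params$threshold, x$params$err_perception,
              x$params$err_execution))
  cat(sprintf("  average cooperation: %.4f\n", x$metrics$avg_cooperation))
  cat(sprintf("  average fusion:      %.4f\n", x$metrics$avg_fusion))
  invisible(x)
}

#' @export
summary.fusion_sim <- function(object, ...) {
  fp <- object$final_pop
  rules <- paste0(fp$rule_s, fp$rule_u, fp$rule_d)
  tab <- sort(table(rules), decreasing = TRUE)
  out <- list(
    params = object$params,
    avg_cooperation = object$metrics$avg_cooperation,
    avg_fusion = object$metrics$avg_fusion,
    games_played = object$metrics$cum_games,
    donations = object$metrics$cum_donations,
    final_mean_fusion = mean(fp$fusion),
    modal_rule = names(tab)[1],
    rule_table = tab
  )
  class(out) <- "summary.fusion_sim"
  out
}

#' @export
print.summary.fusion_sim <- function(x, ...) {
  cat(sprintf("Average cooperation %.4f over %.0f games (%.0f donations)\n",
              x$avg_cooperation, x$games_played, x$donations))
  cat(sprintf("Average fusion %.4f; final-generation mean fusion %.4f\n",
              x$avg_fusion, x$final_mean_fusion))
  cat(sprintf("Modal final action rule (s,u,d): %s\n", x$modal_rule))
  cat("Final rule frequencies:\n")
  print(x$rule_table)
  invisible(x)
}

#' @export
as.data.frame.fusion_sim <- function(x, ...) {
  if (is.null(x$trajectory)) {
    stop("run_model() was called with record = FALSE; no trajectory stored")
  }
  x$trajectory
}

#' Plot a simulation trajectory
#'
#' Cumulative average cooperation and average fusion against generation.
#'
#' @param x A `fusion_sim` object.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.fusion_sim <- function(x, ...) {
  tr <- as.data.frame(x)
  graphics::matplot(tr$generation, cbind(tr$avg_coop, tr$avg_fusion),
                    type = "l", lty = 1, lwd = 2,
                    col = c("#1b6ca8", "#c8401f"),
                    xlab = "generation", ylab = "cumulative average",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright",
                   legend = c("avg cooperation", "avg fusion"),
                   col = c("#1b6ca8", "#c8401f"), lty = 1, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Replicated runs with seed averaging
#'
#' Runs the same configuration under several seeds and averages the
#' cumulative metrics arithmetically across seeds, the convention used for
#' all reported results.
#'
#' @param params A [sim_params()] object; its `seed` field seeds the first
#'   replicate when `seeds` is not given.
#' @param n_seeds Number of replicate runs.
#' @param seeds Optional explicit integer seed vector (overrides
#'   `n_seeds`).
#' @param engine Passed to [run_model()].
#' @param record Keep per-run trajectories? The seed-averaged trajectory
#'   is always computed when `TRUE`.
#' @return An object of class `fusion_experiment`: `params`, `seeds`,
#'   `per_seed` (data frame of final metrics per seed),
#'   `avg_cooperation`, `avg_fusion` (seed-averaged), `avg_trajectory`
#'   (data frame, seed-averaged curves) and `runs` (list of `fusion_sim`).
#' @examples
#' p <- sim_params(n_agents = 20, games_per_gen = 100, generations = 10)
#' ex <- run_experiment(p, n_seeds = 2)
#' ex
#' @export
run_experiment <- function(params, n_seeds = 3L, seeds = NULL,
                           engine = "cpp", record = TRUE) {
  if (is.null(seeds)) seeds <- params$seed + seq_len(n_seeds) - 1L
  stopifnot(length(seeds) >= 1L)
  runs <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    pk <- params
    pk$seed <- as.integer(seeds[k])
    runs[[k]] <- run_model(pk, engine = engine, record = record)
  }
  per_seed <- data.frame(
    seed = as.integer(seeds),
    avg_cooperation = vapply(runs, function(r) r$metrics$avg_cooperation,
                             numeric(1)),
    avg_fusion = vapply(runs, function(r) r$metrics$avg_fusion, numeric(1))
  )
  avg_traj <- NULL
  if (record) {
    avg_traj <- data.frame(
      generation = runs[[1]]$trajectory$generation,
      avg_coop = rowMeans(sapply(runs, function(r) r$trajectory$avg_coop)),
      avg_fusion = rowMeans(sapply(runs,
                                   function(r) r$trajectory$avg_fusion))
    )
  }
  structure(
    list(params = params, seeds = as.integer(seeds), per_seed = per_seed,
         avg_cooperation = mean(per_seed$avg_cooperation),
         avg_fusion = mean(per_seed$avg_fusion),
         avg_trajectory = avg_traj, runs = runs),
    class = "fusion_experiment"
  )
}

#' @export
print.fusion_experiment <- function(x, ...) {
  cat(sprintf("Seed-averaged experiment (%d seeds: %s)\n",
              length(x$seeds), paste(x$seeds, collapse = ", ")))
  cat(sprintf("  average cooperation: %.4f\n", x$avg_cooperation))
  cat(sprintf("  average fusion:      %.4f\n", x$avg_fusion))
  cat("Per seed:\n")
  print(x$per_seed, row.names = FALSE)
  invisible(x)
}

#' @export
summary.fusion_experiment <- function(object, ...) {
  data.frame(
    metric = c("avg_cooperation", "avg_fusion"),
    mean = c(object$avg_cooperation, object$avg_fusion),
    sd = c(stats::sd(object$per_seed$avg_cooperation),
           stats::sd(object$per_seed$avg_fusion)),
    min = c(min(object$per_seed$avg_cooperation),
            min(object$per_seed$avg_fusion)),
    max = c(max(object$per_seed$avg_cooperation),
            max(object$per_seed$avg_fusion))
  )
}

#' @export
plot.fusion_experiment <- function(x, ...) {
  if (is.null(x$avg_trajectory)) stop("no trajectory recorded")
  tr <- x$avg_trajectory
  graphics::matplot(tr$generation, cbind(tr$avg_coop, tr$avg_fusion),
                    type = "l", lty = 1, lwd = 2,
                    col = c("#1b6ca8", "#c8401f"),
                    xlab = "generation", ylab = "cumulative average",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright",
                   legend = c("avg cooperation", "avg fusion"),
                   col = c("#1b6ca8", "#c8401f"), lty = 1, lwd = 2,
                   bty = "n")
  invisible(x)
}
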