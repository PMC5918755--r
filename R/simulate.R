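#' Run the society simulation
#'
#' Executes `replications` independent runs of the configured artificial
#' society: `horizon` dyadic interactions, each between a uniformly sampled
#' pair of agents who act simultaneously on their beliefs about the
#' partner's group and then update those beliefs by exponential smoothing,
#' with learning rates that are constant or conformity-modulated, plus the
#' configured enlightenment schedule. Group-mean out-group willingness and
#' group-mean learning rates are recorded on a log-spaced checkpoint grid.
#'
#' Each replication runs on its own set of named random substreams derived
#' from the master seed (initialization, dyad sampling, the two groups'
#' action draws, interventions), so results are reproducible bit-for-bit
#' and in-group dynamics cannot perturb cross-group dynamics.
#'
#' @param config A [model_config()] or [scenario_preset()].
#' @param seed Master seed (default `config$seed`).
#' @param replications Number of replications (default `config$n_replications`).
#' @param checkpoints Approximate checkpoint count (default `config$checkpoints`).
#' @param trace Record a per-interaction trace (dyad, actions, learning
#'   rates, updated beliefs)? Only sensible for short horizons.
#' @return A `trust_sim` object: a list with `trajectories` (tibble:
#'   `replication`, `time`, `mean_dominant_to_subordinate`,
#'   `mean_subordinate_to_dominant`, `mean_alpha_dominant`,
#'   `mean_alpha_subordinate`), `summaries` (one row per replication:
#'   `convergence_time`, terminal means, `unrecovered_trust`,
#'   `decline_recovery_ratio`, `seed`), `initial_states`, `final_states`,
#'   `replacement_events`, optional `traces`, and the resolved `config`.
#' @examples
#' sim <- simulate_society(model_config(horizon = 1e4, n_replications = 2,
#'                                      checkpoints = 50), seed = 1)
#' glance(sim)
#' @export
simulate_society <- function(config,
                             seed = config$seed,
                             replications = config$n_replications,
                             checkpoints = config$checkpoints,
                             trace = FALSE) {
  validate_config(config)
  seed <- as.numeric(seed)
  grid <- checkpoint_grid(config$horizon, checkpoints)
  ecfg <- as_engine_config(config)
  reps <- purrr::map(seq_len(replications), function(r) {
    cpp_run_replication(ecfg, seed, r, grid, trace)
  })

  trajectories <- purrr::list_rbind(purrr::imap(reps, function(x, r) {
    tr <- tibble::as_tibble(x$trajectory)
    tr$replication <- as.integer(r)
    tr[, c("replication", setdiff(names(tr), "replication"))]
  }))

  state_tbl <- function(m) {
    tibble::tibble(
      agent = seq_len(nrow(m)),
      group = factor(ifelse(m[, 1] == 1, "dominant", "subordinate"),
                     levels = c("dominant", "subordinate")),
      belief_toward_dominant = m[, 2],
      belief_toward_subordinate = m[, 3])
  }

  has_interv <- config$intervention_mode != "none"
  t_e <- config$t_enlightenment
  summaries <- purrr::list_rbind(purrr::imap(reps, function(x, r) {
    tr <- tibble::as_tibble(x$trajectory)
    last <- tr[nrow(tr), ]
    tibble::tibble(
      replication = as.integer(r),
      convergence_time = convergence_time(tr),
      terminal_dominant_to_subordinate = last$mean_dominant_to_subordinate,
      terminal_subordinate_to_dominant = last$mean_subordinate_to_dominant,
      unrecovered_trust = if (has_interv && config$horizon > t_e) {
        unrecovered_trust(tr, t_e, delta = config$horizon - t_e)
      } else NA_real_,
      decline_recovery_ratio = if (has_interv && t_e > 0 &&
                                   config$horizon > t_e) {
        decline_recovery_ratio(tr, t_e)
      } else NA_real_,
      seed = seed
    )
  }))

  events <- purrr::list_rbind(purrr::imap(reps, function(x, r) {
    if (length(x$replacement_times) == 0) return(NULL)
    tibble::tibble(replication = as.integer(r),
                   time = as.numeric(x$replacement_times),
                   agent = as.integer(x$replacement_agents))
  }))

  out <- list(
    config = config,
    seed = seed,
    replications = as.integer(replications),
    checkpoint_times = grid,
    trajectories = trajectories,
    summaries = summaries,
    initial_states = purrr::map(reps, function(x) state_tbl(x$initial_state)),
    final_states = purrr::map(reps, function(x) state_tbl(x$final_state)),
    replacement_events = events
  )
  if (trace) {
    out$traces <- purrr::map(reps, function(x) tibble::as_tibble(x$trace))
  }
  structure(out, class = "trust_sim")
}

#' @export
print.trust_sim <- function(x, ...) {
  cat(sprintf("<trust_sim> %d replication(s), horizon %g, seed %g\n",
              x$replications, x$config$horizon, x$seed))
  g <- glance(x)
  cat(sprintf("  terminal willingness: dominant->subordinate %.3f, subordinate->dominant %.3f\n",
              g$terminal_dominant_to_subordinate,
              g$terminal_subordinate_to_dominant))
  if (!is.na(g$mean_convergence_time)) {
    cat(sprintf("  mean convergence time (gap < 1e-4): %.3g\n",
                g$mean_convergence_time))
  }
  if (!is.na(g$mean_unrecovered_trust)) {
    cat(sprintf("  mean unrecovered trust: %.3f\n", g$mean_unrecovered_trust))
  }
  invisible(x)
}

#' Tidy a simulation into its trajectory tibble
#'
#' Returns the per-replication trajectories, one row per replication and
#' checkpoint, ready for dplyr/ggplot2 work or for
#' [aggregate_replications()].
#'
#' @param x A `trust_sim` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy trust_sim
#' @export
tidy.trust_sim <- function(x, ...) {
  x$trajectories
}

#' One-row summary of a simulation
#'
#' Aggregates the per-replication summaries: mean terminal willingness of
#' each group toward the other, the mean convergence time among converged
#' replications (and how many converged), and, when an intervention ran,
#' the mean unrecovered trust and the decline/recovery rate ratio of the
#' aggregate trajectory.
#'
#' @param x A `trust_sim` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance trust_sim
#' @export
glance.trust_sim <- function(x, ...) {
  s <- x$summaries
  conv <- s$convergence_time[!is.na(s$convergence_time)]
  agg <- aggregate_replications(x$trajectories)
  has_interv <- x$config$intervention_mode != "none"
  t_e <- x$config$t_enlightenment
  tibble::tibble(
    replications = x$replications,
    horizon = x$config$horizon,
    terminal_dominant_to_subordinate =
      mean(s$terminal_dominant_to_subordinate),
    terminal_subordinate_to_dominant =
      mean(s$terminal_subordinate_to_dominant),
    n_converged = length(conv),
    mean_convergence_time = if (length(conv) > 0) mean(conv) else NA_real_,
    mean_unrecovered_trust = if (has_interv) mean(s$unrecovered_trust)
                             else NA_real_,
    aggregate_decline_recovery_ratio =
      if (has_interv && t_e > 0 && x$config$horizon > t_e) {
        decline_recovery_ratio(agg, t_e)
      } else NA_real_
  )
}
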