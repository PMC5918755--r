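# Shared fixtures and the reference replay oracle.

# A small, fast configuration used across tests.
small_config <- function(...) {
  defaults <- list(n_dominant = 12, n_subordinate = 4, horizon = 500,
                   n_replications = 1, checkpoints = 30)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# Replays a recorded engine trace step by step through the plain-R
# reference implementation (brute-force norms, scalar updates) and returns
# the largest absolute deviation seen in any learning rate or updated
# belief. Verifies that the engine's incremental-norm fast path computes
# exactly the dynamics the model defines.
replay_max_deviation <- function(config, seed) {
  sim <- simulate_society(config, seed = seed, replications = 1, trace = TRUE)
  init <- sim$initial_states[[1]]
  trace <- sim$traces[[1]]
  group <- as.character(init$group)
  bel <- list(dominant = init$belief_toward_dominant,
              subordinate = init$belief_toward_subordinate)
  worst <- 0
  for (k in seq_len(nrow(trace))) {
    row <- trace[k, ]
    a <- row$agent_a; b <- row$agent_b
    ga <- group[a]; gb <- group[b]
    bel_a <- bel[[gb]][a]
    bel_b <- bel[[ga]][b]
    if (config$alpha_mode == "constant") {
      alpha_a <- alpha_b <- config$alpha_constant
    } else {
      alpha_a <- learning_rate(bel_a,
                               group_norm(bel[[gb]][group == ga],
                                          config$norm_variant))
      alpha_b <- learning_rate(bel_b,
                               group_norm(bel[[ga]][group == gb],
                                          config$norm_variant))
    }
    new_a <- update_belief(bel_a, row$action_b, alpha_a)
    new_b <- update_belief(bel_b, row$action_a, alpha_b)
    worst <- max(worst,
                 abs(alpha_a - row$alpha_a), abs(alpha_b - row$alpha_b),
                 abs(new_a - row$new_belief_a), abs(new_b - row$new_belief_b))
    bel[[gb]][a] <- new_a
    bel[[ga]][b] <- new_b
  }
  # final state must agree too
  final <- sim$final_states[[1]]
  worst <- max(worst,
               abs(bel$dominant - final$belief_toward_dominant),
               abs(bel$subordinate - final$belief_toward_subordinate))
  worst
}

# terminal means of each group toward the other, averaged over replications
terminal_means <- function(sim) {
  g <- glance(sim)
  c(dominant = g$terminal_dominant_to_subordinate,
    subordinate = g$terminal_subordinate_to_dominant)
}
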