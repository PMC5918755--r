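#' Initialize a population of agents
#'
#' Draws every agent's two directed beliefs from the configured prior
#' distributions. Dominant agents' beliefs toward the subordinate group come
#' from the (by default prejudiced) dominant out-group prior, subordinate
#' agents' beliefs toward the dominant group from the subordinate out-group
#' prior, and in-group beliefs from the in-group priors. Truncated-normal
#' priors are rejection-sampled into (0, 1).
#'
#' The draws come from the same named random substreams the simulation
#' engine uses, so `init_population(cfg, seed, r)` is exactly the state at
#' t = 0 of replication `r` of [simulate_society()] under the same seed.
#'
#' @param config A [model_config()].
#' @param seed Master seed (defaults to `config$seed`).
#' @param replication Replication index (>= 1) whose substreams to use.
#' @return A tibble with one row per agent and columns `agent`, `group`
#'   (`"dominant"`/`"subordinate"`), `belief_toward_dominant`,
#'   `belief_toward_subordinate`, carrying attribute `interaction_count = 0`.
#' @examples
#' pop <- init_population(model_config(horizon = 0))
#' dplyr::count(pop, group)
#' @export
init_population <- function(config, seed = config$seed, replication = 1) {
  validate_config(config)
  m <- cpp_init_population(as_engine_config(config), as.numeric(seed),
                           as.numeric(replication))
  pop <- tibble::tibble(
    agent = seq_len(nrow(m)),
    group = factor(ifelse(m[, 1] == 1, "dominant", "subordinate"),
                   levels = c("dominant", "subordinate")),
    belief_toward_dominant = m[, 2],
    belief_toward_subordinate = m[, 3]
  )
  attr(pop, "interaction_count") <- 0
  pop
}

#' Sample one dyad uniformly from all unordered pairs
#'
#' Every unordered pair of distinct agents is equally likely, so the
#' probability that an interaction crosses group lines is proportional to
#' the product of the group sizes. Uses R's RNG (`set.seed()` controls it).
#'
#' @param population A population tibble (only its row count is used).
#' @return Integer vector of two distinct agent indices.
#' @export
sample_dyad <- function(population) {
  n <- nrow(population)
  if (n < 2) abort("need at least 2 agents to sample a dyad")
  sample.int(n, 2L, replace = FALSE)
}

#' Choose an action from a belief
#'
#' With the default Bernoulli rule the agent collaborates with probability
#' exactly equal to its belief toward the partner's group; the threshold
#' variant collaborates iff the belief is at least 0.5. Uses R's RNG.
#'
#' @param belief Probability in \[0, 1\] (vectorised).
#' @param rule `"bernoulli"` or `"threshold"`.
#' @return Integer vector of actions: 1 = collaborate, 0 = defect.
#' @export
choose_action <- function(belief, rule = c("bernoulli", "threshold")) {
  rule <- match.arg(rule)
  if (any(!is.finite(belief)) || any(belief < 0) || any(belief > 1)) {
    abort("belief must lie in [0, 1]")
  }
  if (rule == "bernoulli") {
    as.integer(runif(length(belief)) < belief)
  } else {
    as.integer(belief >= 0.5)
  }
}

#' Exponential-smoothing belief update
#'
#' The updated belief is the convex combination
#' `alpha * action + (1 - alpha) * belief`: the agent moves its group-level
#' belief toward the partner's observed action by its learning rate. With
#' `alpha = 0` no learning occurs and the belief is a fixed point.
#'
#' @param belief Current belief in \[0, 1\] (vectorised).
#' @param partner_action 0 (defect) or 1 (collaborate).
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated belief, guaranteed in \[0, 1\].
#' @examples
#' update_belief(0.5, 1, 0.25) # 0.625
#' @export
update_belief <- function(belief, partner_action, alpha) {
  if (any(!is.finite(belief)) || any(belief < 0) || any(belief > 1)) {
    abort("belief must lie in [0, 1]")
  }
  if (!all(partner_action %in% c(0, 1))) {
    abort("partner_action must be 0 or 1")
  }
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1)) {
    abort("alpha must lie in [0, 1]")
  }
  alpha * partner_action + (1 - alpha) * belief
}

# Directed belief of agents toward a target group, as a column name.
belief_column <- function(target_group) {
  paste0("belief_toward_", target_group)
}

#' Advance the society by one dyadic interaction (reference implementation)
#'
#' A plain-R, one-step-at-a-time version of the simulation step, intended
#' for inspection and as an independent check of the compiled engine (which
#' reproduces the same arithmetic with incrementally maintained norms). One
#' dyad is sampled; both agents act simultaneously on their pre-interaction
#' beliefs toward the partner's group; each then updates that same directed
#' belief using the partner's action and its learning rate (constant, or
#' its distance from the group norm under conformity, evaluated on the
#' pre-interaction belief configuration). Exactly the two participants'
#' beliefs change. Uses R's RNG.
#'
#' @param population Population tibble from [init_population()].
#' @param config A [model_config()].
#' @param dyad Optional pair of agent indices (default: sampled).
#' @param actions Optional pair of actions for the two dyad members
#'   (default: drawn by `choose_action()`).
#' @return The updated population tibble; the `interaction_count` attribute
#'   is incremented by one.
#' @export
step_interaction <- function(population, config, dyad = NULL, actions = NULL) {
  if (is.null(dyad)) dyad <- sample_dyad(population)
  a <- dyad[1]; b <- dyad[2]
  if (a == b) abort("dyad members must be distinct")
  ga <- as.character(population$group[a])
  gb <- as.character(population$group[b])
  col_a <- belief_column(gb) # a's belief toward b's group
  col_b <- belief_column(ga)
  bel_a <- population[[col_a]][a]
  bel_b <- population[[col_b]][b]
  if (is.null(actions)) {
    actions <- c(choose_action(bel_a, config$action_rule),
                 choose_action(bel_b, config$action_rule))
  }
  if (config$alpha_mode == "constant") {
    alpha_a <- alpha_b <- config$alpha_constant
  } else {
    peers_a <- population[[col_a]][population$group == ga]
    peers_b <- population[[col_b]][population$group == gb]
    alpha_a <- learning_rate(bel_a, group_norm(peers_a, config$norm_variant))
    alpha_b <- learning_rate(bel_b, group_norm(peers_b, config$norm_variant))
  }
  population[[col_a]][a] <- update_belief(bel_a, actions[2], alpha_a)
  population[[col_b]][b] <- update_belief(bel_b, actions[1], alpha_b)
  attr(population, "interaction_count") <-
    (attr(population, "interaction_count") %||% 0) + 1
  population
}

`%||%` <- function(x, y) if (is.null(x)) y else x
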