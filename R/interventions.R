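#' Enlighten the dominant group of a population
#'
#' Sets every dominant agent's two directed beliefs to its enlightened
#' baseline value: enlightened individuals see no difference between the
#' groups and treat them the same. Baselines are drawn from U(0, 1) via R's
#' RNG unless supplied. Subordinate agents are untouched and group sizes are
#' conserved. Re-applying with the same baselines is a no-op, which is how
#' the simulation engine realises "replacement every period": a frozen
#' baseline re-imposed each period cannot drift.
#'
#' @param population Population tibble from [init_population()].
#' @param baselines Optional numeric vector, one value per dominant agent.
#' @return The modified population tibble.
#' @export
apply_instant_enlightenment <- function(population, baselines = NULL) {
  dom <- which(population$group == "dominant")
  if (is.null(baselines)) baselines <- runif(length(dom))
  if (length(baselines) != length(dom)) {
    abort("need one baseline value per dominant agent")
  }
  population$belief_toward_dominant[dom] <- baselines
  population$belief_toward_subordinate[dom] <- baselines
  population
}

#' Replace one dominant agent with an enlightened individual
#'
#' Gradual generational replacement: a uniformly chosen dominant agent (or
#' the given `member`) has both directed beliefs redrawn equal from U(0, 1),
#' modelling the death of a prejudiced individual and the birth of an
#' unprejudiced one. Unless configured otherwise the newcomer learns
#' normally afterwards and is subject to the same conformity as everyone
#' else.
#'
#' @param population Population tibble.
#' @param member Optional index (within the dominant group's agent indices)
#'   of the agent to replace; default: sampled uniformly via R's RNG.
#' @param value Optional enlightened belief value; default: U(0, 1) draw.
#' @return The modified population tibble.
#' @export
apply_gradual_replacement <- function(population, member = NULL, value = NULL) {
  dom <- which(population$group == "dominant")
  if (length(dom) == 0) abort("population has no dominant agents")
  if (is.null(member)) member <- dom[sample.int(length(dom), 1L)]
  if (!member %in% dom) abort("member must be a dominant agent")
  if (is.null(value)) value <- runif(1)
  population$belief_toward_dominant[member] <- value
  population$belief_toward_subordinate[member] <- value
  population
}
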