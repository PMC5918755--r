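#' Build a simulation configuration
#'
#' A `trust_config` holds every parameter of a run of the artificial society:
#' group sizes, initial-belief (prior) distributions, the learning-rate mode,
#' the group-norm variant used under conformity, the intervention schedule,
#' the horizon and replication/seed bookkeeping.
#'
#' The society has a dominant group of `n_dominant` agents and a subordinate
#' group of `n_subordinate` agents. Each agent holds two directed beliefs,
#' one toward each group, interpreted as its probability of choosing the
#' collaborative strategy toward a member of that group. Prejudice enters
#' through the initial distributions: by default the dominant group's
#' out-group belief is drawn from U(0, `theta`) with `theta < 1`, while the
#' subordinate group's out-group belief is drawn from U(0, 1), so the
#' dominant group systematically underestimates the subordinate group's
#' willingness to collaborate.
#'
#' Priors are given as two-parameter specifications. For
#' `prior_family = "uniform"` the parameters are the lower and upper bound;
#' for `"truncated_normal"` they are the mean and standard deviation of a
#' normal rejection-sampled into (0, 1). Explicit `prior_*` arguments
#' override the defaults implied by `theta`.
#'
#' @param n_dominant,n_subordinate Group sizes (positive integers).
#' @param theta Upper bound of the dominant group's default uniform
#'   out-group prior, in (0, 1]. `theta = 1` removes the initial bias.
#' @param prior_family `"uniform"` or `"truncated_normal"`; applies to the
#'   two out-group priors unless they are given explicitly.
#' @param prior_dominant_out,prior_subordinate_out Numeric length-2 vectors,
#'   parameters of the out-group priors (see Details), or `NULL` for the
#'   family default: uniform `c(0, theta)` / `c(0, 1)`, truncated normal
#'   `c(0.25, 0.2)` / `c(0.5, 0.2)`.
#' @param prior_dominant_in,prior_subordinate_in In-group priors, always
#'   uniform; default `c(0, 1)`. In-group beliefs evolve independently of
#'   the cross-group dynamics and do not affect cross-group results.
#' @param alpha_mode `"constant"` (fixed learning rate `alpha_constant`) or
#'   `"conformity"` (the learning rate of an agent equals the absolute
#'   distance between its belief and its group's norm toward the target
#'   group, recomputed every interaction).
#' @param alpha_constant Learning rate in \[0, 1\], used when
#'   `alpha_mode = "constant"`.
#' @param norm_variant How the group norm is computed under conformity:
#'   `"inverse_pairwise_distance"` (weights are reciprocals of each member's
#'   total absolute belief distance to all peers), `"distance_from_mean"` or
#'   `"distance_from_median"` (weights are reciprocals of the distance to
#'   the group mean or median).
#' @param action_rule `"bernoulli"` (collaborate with probability equal to
#'   the belief; default) or `"threshold"` (collaborate iff belief >= 0.5).
#' @param intervention_mode `"none"`, `"instant_enlightenment"` (from
#'   `t_enlightenment` onward every dominant agent holds an enlightened
#'   baseline belief, equal toward both groups), or `"gradual_replacement"`
#'   (one randomly chosen dominant agent is replaced by an enlightened one
#'   every `replacement_interval` interactions).
#' @param t_enlightenment Interaction count at which the intervention
#'   schedule starts.
#' @param replacement_interval Interactions between gradual replacements.
#' @param baseline_mode `"frozen"` (enlightened baselines are drawn once at
#'   `t_enlightenment` and re-imposed every period, so they never drift) or
#'   `"redraw"` (a fresh enlightened generation is drawn every period).
#' @param replacement_learns Should gradually inserted enlightened agents
#'   keep learning afterwards? Default `TRUE`.
#' @param horizon Number of dyadic interactions to simulate. One period of
#'   model time is one interaction.
#' @param n_replications Default number of independent replications.
#' @param seed Master seed; every random stream of a run derives from it.
#' @param checkpoints Approximate number of log-spaced recording times.
#' @param audit_interval If positive, every `audit_interval` interactions
#'   the incrementally maintained norm state is checked against a
#'   from-scratch recomputation (aborting on divergence). 0 disables.
#'
#' @return A `trust_config` object (a named list).
#' @examples
#' cfg <- model_config(horizon = 1e4, n_replications = 2)
#' cfg
#' @seealso [scenario_preset()], [simulate_society()]
#' @export
model_config <- function(n_dominant = 80,
                         n_subordinate = 20,
                         theta = 0.5,
                         prior_family = c("uniform", "truncated_normal"),
                         prior_dominant_out = NULL,
                         prior_subordinate_out = NULL,
                         prior_dominant_in = c(0, 1),
                         prior_subordinate_in = c(0, 1),
                         alpha_mode = c("conformity", "constant"),
                         alpha_constant = 0.25,
                         norm_variant = c("inverse_pairwise_distance",
                                          "distance_from_mean",
                                          "distance_from_median"),
                         action_rule = c("bernoulli", "threshold"),
                         intervention_mode = c("none",
                                               "instant_enlightenment",
                                               "gradual_replacement"),
                         t_enlightenment = 1e4,
                         replacement_interval = 100,
                         baseline_mode = c("frozen", "redraw"),
                         replacement_learns = TRUE,
                         horizon = 1e7,
                         n_replications = 10,
                         seed = 1L,
                         checkpoints = 200,
                         audit_interval = 0) {
  prior_family <- match.arg(prior_family)
  alpha_mode <- match.arg(alpha_mode)
  norm_variant <- match.arg(norm_variant)
  action_rule <- match.arg(action_rule)
  intervention_mode <- match.arg(intervention_mode)
  baseline_mode <- match.arg(baseline_mode)

  if (is.null(prior_dominant_out)) {
    prior_dominant_out <- if (prior_family == "uniform") c(0, theta) else c(0.25, 0.2)
  }
  if (is.null(prior_subordinate_out)) {
    prior_subordinate_out <- if (prior_family == "uniform") c(0, 1) else c(0.5, 0.2)
  }

  cfg <- structure(list(
    n_dominant = as.integer(n_dominant),
    n_subordinate = as.integer(n_subordinate),
    theta = as.numeric(theta),
    prior_family = prior_family,
    prior_dominant_out = as.numeric(prior_dominant_out),
    prior_subordinate_out = as.numeric(prior_subordinate_out),
    prior_dominant_in = as.numeric(prior_dominant_in),
    prior_subordinate_in = as.numeric(prior_subordinate_in),
    alpha_mode = alpha_mode,
    alpha_constant = as.numeric(alpha_constant),
    norm_variant = norm_variant,
    action_rule = action_rule,
    intervention_mode = intervention_mode,
    t_enlightenment = as.numeric(t_enlightenment),
    replacement_interval = as.numeric(replacement_interval),
    baseline_mode = baseline_mode,
    replacement_learns = isTRUE(replacement_learns),
    horizon = as.numeric(horizon),
    n_replications = as.integer(n_replications),
    seed = as.integer(seed),
    checkpoints = as.integer(checkpoints),
    audit_interval = as.numeric(audit_interval)
  ), class = "trust_config")
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every bound and cross-field requirement of a [model_config()]
#' object and aborts with an informative message on the first violation.
#'
#' @param config A `trust_config` or a plain named list with the same fields.
#' @return The validated `trust_config`, invisibly usable in a pipe.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) abort("`config` must be a list or trust_config")
  required <- c("n_dominant", "n_subordinate", "theta", "prior_family",
                "prior_dominant_out", "prior_subordinate_out",
                "prior_dominant_in", "prior_subordinate_in",
                "alpha_mode", "alpha_constant", "norm_variant", "action_rule",
                "intervention_mode", "t_enlightenment", "replacement_interval",
                "baseline_mode", "replacement_learns", "horizon",
                "n_replications", "seed", "checkpoints", "audit_interval")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    abort(paste0("config is missing fields: ", paste(missing, collapse = ", ")))
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) abort(paste0("invalid config: ", msg))
  chk(config$n_dominant >= 1, "n_dominant must be a positive count")
  chk(config$n_subordinate >= 1, "n_subordinate must be a positive count")
  chk(config$theta > 0 && config$theta <= 1,
      "theta must lie in (0, 1]")
  chk(config$prior_family %in% c("uniform", "truncated_normal"),
      "unknown prior_family")
  for (nm in c("prior_dominant_out", "prior_subordinate_out",
               "prior_dominant_in", "prior_subordinate_in")) {
    p <- config[[nm]]
    chk(is.numeric(p) && length(p) == 2 && all(is.finite(p)),
        paste0(nm, " must be two finite numbers"))
    family <- if (grepl("_in$", nm)) "uniform" else config$prior_family
    if (family == "uniform") {
      chk(p[1] >= 0 && p[2] <= 1 && p[1] < p[2],
          paste0(nm, ": uniform bounds must satisfy 0 <= lower < upper <= 1"))
    } else {
      chk(p[2] > 0, paste0(nm, ": truncated-normal sd must be positive"))
    }
  }
  chk(config$alpha_mode %in% c("constant", "conformity"), "unknown alpha_mode")
  if (config$alpha_mode == "constant") {
    chk(is.numeric(config$alpha_constant) &&
          config$alpha_constant >= 0 && config$alpha_constant <= 1,
        "alpha_constant must lie in [0, 1] when alpha_mode = \"constant\"")
  }
  chk(config$norm_variant %in% c("inverse_pairwise_distance",
                                 "distance_from_mean", "distance_from_median"),
      "unknown norm_variant")
  chk(config$action_rule %in% c("bernoulli", "threshold"), "unknown action_rule")
  chk(config$intervention_mode %in% c("none", "instant_enlightenment",
                                      "gradual_replacement"),
      "unknown intervention_mode")
  chk(config$t_enlightenment >= 0, "t_enlightenment must be >= 0")
  chk(config$replacement_interval >= 1, "replacement_interval must be >= 1")
  chk(config$baseline_mode %in% c("frozen", "redraw"), "unknown baseline_mode")
  chk(config$horizon >= 0, "horizon must be >= 0")
  chk(config$n_replications >= 1, "n_replications must be >= 1")
  chk(is.finite(config$seed), "seed must be a finite integer")
  chk(config$checkpoints >= 1, "checkpoints must be >= 1")
  chk(config$audit_interval >= 0, "audit_interval must be >= 0")
  if (!inherits(config, "trust_config")) class(config) <- "trust_config"
  config
}

#' @export
print.trust_config <- function(x, ...) {
  cat("<trust_config>\n")
  fmt_prior <- function(p, family) {
    if (family == "uniform") sprintf("U(%g, %g)", p[1], p[2])
    else sprintf("N(%g, %g) truncated to (0,1)", p[1], p[2])
  }
  cat(sprintf("  groups: dominant %d, subordinate %d\n",
              x$n_dominant, x$n_subordinate))
  cat(sprintf("  out-group priors: dominant %s, subordinate %s\n",
              fmt_prior(x$prior_dominant_out, x$prior_family),
              fmt_prior(x$prior_subordinate_out, x$prior_family)))
  if (x$alpha_mode == "constant") {
    cat(sprintf("  learning: constant alpha = %g\n", x$alpha_constant))
  } else {
    cat(sprintf("  learning: conformity (norm: %s)\n", x$norm_variant))
  }
  if (x$intervention_mode != "none") {
    cat(sprintf("  intervention: %s from t = %g", x$intervention_mode,
                x$t_enlightenment))
    if (x$intervention_mode == "gradual_replacement") {
      cat(sprintf(", every %g periods", x$replacement_interval))
    }
    cat("\n")
  }
  cat(sprintf("  horizon: %g interactions, %d replication(s), seed %d\n",
              x$horizon, x$n_replications, x$seed))
  invisible(x)
}

# Engine-facing representation: priors as family/p1/p2 sub-lists.
as_engine_config <- function(config) {
  pr <- function(p, family) list(family = family, p1 = p[1], p2 = p[2])
  list(
    n_dominant = config$n_dominant,
    n_subordinate = config$n_subordinate,
    prior_dominant_out = pr(config$prior_dominant_out, config$prior_family),
    prior_subordinate_out = pr(config$prior_subordinate_out, config$prior_family),
    prior_dominant_in = pr(config$prior_dominant_in, "uniform"),
    prior_subordinate_in = pr(config$prior_subordinate_in, "uniform"),
    alpha_mode = config$alpha_mode,
    alpha_constant = config$alpha_constant,
    norm_variant = config$norm_variant,
    action_rule = config$action_rule,
    intervention_mode = config$intervention_mode,
    t_enlightenment = config$t_enlightenment,
    replacement_interval = config$replacement_interval,
    baseline_mode = config$baseline_mode,
    replacement_learns = config$replacement_learns,
    horizon = config$horizon,
    audit_interval = config$audit_interval
  )
}

#' Log-spaced checkpoint grid for a horizon
#'
#' Returns an increasing integer vector of recording times containing 0,
#' the horizon, and approximately `n` log-spaced times in between. All of
#' the package's trajectory plots use logarithmic time, so this grid gives
#' uniform visual coverage at a storage cost independent of the horizon.
#'
#' @param horizon Total number of interactions.
#' @param n Approximate number of checkpoints (default 200).
#' @return Numeric vector of strictly increasing times.
#' @export
checkpoint_grid <- function(horizon, n = 200) {
  horizon <- as.numeric(horizon)
  if (horizon <= 0) return(0)
  grid <- unique(c(0, round(10^seq(0, log10(horizon), length.out = n)), horizon))
  sort(grid[grid <= horizon])
}

#' Write a configuration to a YAML file
#'
#' Every scenario preset round-trips losslessly through this format:
#' `read_config(write_config(cfg, f))` reproduces `cfg` exactly.
#'
#' @param config A `trust_config`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  out$replacement_learns <- as.logical(out$replacement_learns)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' @param path File path written by [write_config()] (or hand-authored with
#'   the same flat schema; missing fields fall back to [model_config()]
#'   defaults).
#' @return A validated `trust_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- unclass(model_config(horizon = 1e7))
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, raw)
  for (nm in c("n_dominant", "n_subordinate", "n_replications",
               "seed", "checkpoints")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  for (nm in c("theta", "alpha_constant", "t_enlightenment",
               "replacement_interval", "horizon", "audit_interval",
               "prior_dominant_out", "prior_subordinate_out",
               "prior_dominant_in", "prior_subordinate_in")) {
    cfg[[nm]] <- as.numeric(cfg[[nm]])
  }
  class(cfg) <- "trust_config"
  validate_config(cfg)
}
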