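#' Scenario presets
#'
#' The preset registry encodes every society configuration studied with the
#' model: the base case with constant learning speed, the base conformity
#' case, variations in the magnitude of initial prejudice, population size,
#' relative group sizes, generally collaborative and generally distrustful
#' societies, truncated-normal initial beliefs, and the enlightenment
#' interventions (instantaneous, delayed, and gradual generational
#' replacement).
#'
#' `scenario_presets()` lists the registry; `scenario_preset(name)` returns
#' the full configuration for one entry (with optional field overrides).
#'
#' @return `scenario_presets()`: a tibble with columns `name` and `note`.
#' @examples
#' scenario_presets()
#' scenario_preset("base_conformity")
#' @name scenario_presets
NULL

preset_registry <- function() {
  tn <- function(sd) list(prior_family = "truncated_normal",
                          prior_dominant_out = c(0.25, sd),
                          prior_subordinate_out = c(0.5, sd))
  large <- list(n_dominant = 800, n_subordinate = 200)
  list(
    base_constant_alpha = list(
      note = "80/20 society, theta 0.5, constant learning rate 0.25; beliefs converge near 0.3",
      args = list(alpha_mode = "constant", horizon = 1e6)),
    base_conformity = list(
      note = "80/20 society, theta 0.5, conformity-modulated learning; stigma persists to the horizon",
      args = list()),
    stigma_strong = list(
      note = "severe initial prejudice: dominant out-group prior U(0, 0.1)",
      args = list(theta = 0.1)),
    stigma_mild = list(
      note = "mild initial prejudice: dominant out-group prior U(0, 0.9)",
      args = list(theta = 0.9)),
    stigma_trivial = list(
      note = "near-absent initial prejudice: dominant out-group prior U(0, 0.99)",
      args = list(theta = 0.99)),
    large_population = list(
      note = "1000-agent society (800/200), otherwise the base conformity case",
      args = large),
    enlightenment = list(
      note = "instant enlightenment of the dominant group from t = 1e4 onward",
      args = list(intervention_mode = "instant_enlightenment",
                  t_enlightenment = 1e4, horizon = 1e4 + 1e7)),
    delayed_enlightenment = list(
      note = "instant enlightenment delayed to t = 1e5; see enlightenment_sweep() for the full delay sweep",
      args = list(intervention_mode = "instant_enlightenment",
                  t_enlightenment = 1e5, horizon = 1e5 + 1e7)),
    large_enlightenment = list(
      note = "1000-agent society enlightened at t = 1e5 (same accumulated interactions per individual as the small society at 1e4)",
      args = c(large, list(intervention_mode = "instant_enlightenment",
                           t_enlightenment = 1e5, horizon = 1e5 + 1e7))),
    gradual_replacement = list(
      note = "one randomly chosen dominant member replaced by an enlightened individual every 100 periods",
      args = list(intervention_mode = "gradual_replacement",
                  t_enlightenment = 0, replacement_interval = 100)),
    inverted_sizes = list(
      note = "subordinate group in the majority: 20 dominant / 80 subordinate",
      args = list(n_dominant = 20, n_subordinate = 80)),
    inverted_sizes_large = list(
      note = "large society with inverted sizes: 200 dominant / 800 subordinate",
      args = list(n_dominant = 200, n_subordinate = 800)),
    collaborative = list(
      note = "generally collaborative society: subordinate prior U(0.5, 1), dominant prior U(0.5, 0.75)",
      args = list(prior_dominant_out = c(0.5, 0.75),
                  prior_subordinate_out = c(0.5, 1), theta = 0.75)),
    collaborative_large = list(
      note = "large collaborative society (800/200)",
      args = c(large, list(prior_dominant_out = c(0.5, 0.75),
                           prior_subordinate_out = c(0.5, 1), theta = 0.75))),
    distrustful = list(
      note = "generally distrustful society: subordinate prior U(0, 0.5), dominant prior U(0, 0.25)",
      args = list(prior_dominant_out = c(0, 0.25),
                  prior_subordinate_out = c(0, 0.5), theta = 0.25)),
    distrustful_large = list(
      note = "large distrustful society (800/200)",
      args = c(large, list(prior_dominant_out = c(0, 0.25),
                           prior_subordinate_out = c(0, 0.5), theta = 0.25))),
    truncated_normal_sd_0.1 = list(
      note = "truncated-normal priors: dominant N(0.25, 0.1), subordinate N(0.5, 0.1), both in (0,1)",
      args = tn(0.1)),
    truncated_normal_sd_0.2 = list(
      note = "truncated-normal priors: dominant N(0.25, 0.2), subordinate N(0.5, 0.2), both in (0,1)",
      args = tn(0.2)),
    truncated_normal_sd_0.3 = list(
      note = "truncated-normal priors: dominant N(0.25, 0.3), subordinate N(0.5, 0.3), both in (0,1)",
      args = tn(0.3)),
    truncated_normal_sd_0.4 = list(
      note = "truncated-normal priors: dominant N(0.25, 0.4), subordinate N(0.5, 0.4), both in (0,1)",
      args = tn(0.4)),
    truncated_normal_large = list(
      note = "large society (800/200) with truncated-normal priors, sd 0.2",
      args = c(large, tn(0.2)))
  )
}

#' @rdname scenario_presets
#' @export
scenario_presets <- function() {
  reg <- preset_registry()
  tibble::tibble(name = names(reg),
                 note = purrr::map_chr(reg, "note"))
}

#' @rdname scenario_presets
#' @param name Preset name; see `scenario_presets()` for the registry.
#' @param ... Field overrides passed on to [model_config()], e.g.
#'   `horizon`, `seed`, `n_replications`.
#' @return `scenario_preset()`: a validated `trust_config`.
#' @export
scenario_preset <- function(name, ...) {
  reg <- preset_registry()
  if (!name %in% names(reg)) {
    abort(paste0("unknown preset \"", name, "\"; available: ",
                 paste(names(reg), collapse = ", ")))
  }
  args <- utils::modifyList(reg[[name]]$args, list(...))
  do.call(model_config, args)
}

#' Configurations for a sweep over the time of enlightenment
#'
#' Returns one configuration per enlightenment time, each running
#' `delta` interactions beyond its enlightenment so that unrecovered trust
#' is measured on a common post-enlightenment span.
#'
#' @param t_enlightenment Vector of enlightenment times.
#' @param delta Post-enlightenment span (default 1e7).
#' @param ... Further overrides passed to [model_config()].
#' @return A named list of `trust_config` objects.
#' @export
enlightenment_sweep <- function(t_enlightenment = 10^(3:5), delta = 1e7, ...) {
  cfgs <- purrr::map(t_enlightenment, function(te) {
    model_config(intervention_mode = "instant_enlightenment",
                 t_enlightenment = te, horizon = te + delta, ...)
  })
  names(cfgs) <- paste0("t_e_", format(t_enlightenment, scientific = FALSE,
                                       trim = TRUE))
  cfgs
}
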