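#' Mean willingness of one group toward another
#'
#' Arithmetic mean of the directed beliefs of observer-group members toward
#' the target group: the society-level "willingness to collaborate" that
#' trajectories record at every checkpoint.
#'
#' @param population Population tibble from [init_population()].
#' @param observer,target `"dominant"` or `"subordinate"`.
#' @return Probability in \[0, 1\].
#' @export
mean_willingness <- function(population, observer, target) {
  observer <- match.arg(observer, c("dominant", "subordinate"))
  target <- match.arg(target, c("dominant", "subordinate"))
  rows <- population$group == observer
  if (!any(rows)) abort(paste0("no agents in observer group \"", observer, "\""))
  mean(population[[belief_column(target)]][rows])
}

# shared guard: a trajectory must be single-replication or aggregated
single_trajectory <- function(trajectory) {
  if ("replication" %in% names(trajectory) &&
      length(unique(trajectory$replication)) > 1) {
    abort(paste0("trajectory contains several replications; ",
                 "aggregate_replications() first or filter to one"))
  }
  trajectory[order(trajectory$time), , drop = FALSE]
}

gap_series <- function(trajectory) {
  abs(trajectory$mean_dominant_to_subordinate -
        trajectory$mean_subordinate_to_dominant)
}

#' Time until the two groups' out-group willingness converges
#'
#' The earliest recorded time at which the absolute difference between the
#' dominant group's mean willingness toward the subordinate group and the
#' subordinate group's mean willingness toward the dominant group falls
#' below `threshold`. With no learning (`alpha = 0`) the gap never closes
#' and the sentinel `NA` is returned. Because the gap is evaluated on the
#' checkpoint grid, the crossing time is quantised to grid resolution
#' (about 5% in log time at the default 200 checkpoints).
#'
#' @param trajectory A single-replication or aggregated trajectory tibble.
#' @param threshold Positive convergence threshold (default 1e-4).
#' @return The first crossing time, or `NA` if the gap never falls below
#'   `threshold` within the trajectory.
#' @export
convergence_time <- function(trajectory, threshold = 1e-4) {
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("threshold must be positive")
  }
  trajectory <- single_trajectory(trajectory)
  hit <- which(gap_series(trajectory) < threshold)
  if (length(hit) == 0) NA_real_ else trajectory$time[hit[1]]
}

#' Common belief level at convergence
#'
#' The value at which the two groups' mean out-group willingness meets: the
#' average of the two group means at the first checkpoint where their gap
#' falls below `threshold`. Individual runs keep diffusing after the curves
#' meet (beliefs are driven by binary outcomes, so a single society
#' eventually absorbs near all-collaborate or all-defect), which is why
#' this is measured at the crossing rather than at the horizon, and why it
#' is only meaningful averaged over replications. If the gap never falls
#' below `threshold` on the grid, the terminal average of the two group
#' means is returned.
#'
#' @inheritParams convergence_time
#' @return The common willingness level, a probability.
#' @export
convergence_value <- function(trajectory, threshold = 1e-4) {
  trajectory <- single_trajectory(trajectory)
  hit <- which(gap_series(trajectory) < threshold)
  i <- if (length(hit) == 0) nrow(trajectory) else hit[1]
  mean(c(trajectory$mean_dominant_to_subordinate[i],
         trajectory$mean_subordinate_to_dominant[i]))
}

#' Unrecovered trust after an enlightenment intervention
#'
#' The difference between the dominant and the subordinate group's mean
#' out-group willingness, evaluated at the checkpoint nearest
#' `t_enlightenment + delta`. After the dominant group is enlightened its
#' willingness jumps while the subordinate group recovers only slowly, so
#' a positive value measures trust the society never got back.
#'
#' @param trajectory A single-replication or aggregated trajectory tibble
#'   covering `t_enlightenment + delta`.
#' @param t_enlightenment Time of enlightenment.
#' @param delta Evaluation lag after enlightenment (default 1e7).
#' @return Dominant-minus-subordinate mean willingness at the evaluation
#'   time.
#' @export
unrecovered_trust <- function(trajectory, t_enlightenment, delta = 1e7) {
  trajectory <- single_trajectory(trajectory)
  target <- t_enlightenment + delta
  if (max(trajectory$time) < target) {
    abort(sprintf("trajectory ends at %g, before evaluation time %g",
                  max(trajectory$time), target))
  }
  i <- which.min(abs(trajectory$time - target))
  trajectory$mean_dominant_to_subordinate[i] -
    trajectory$mean_subordinate_to_dominant[i]
}

#' Ratio of trust-decline to trust-recovery rate around enlightenment
#'
#' Compares how fast the subordinate group's willingness toward the
#' dominant group was destroyed before enlightenment with how fast it
#' accrues afterwards. Both rates are mean per-period rates over their
#' span: decline `(w(0) - w(T_e)) / T_e` and recovery
#' `(w(end) - w(T_e)) / (end - T_e)`, where `w` is the subordinate group's
#' mean out-group willingness and `T_e` the (checkpoint nearest the) time
#' of enlightenment. A ratio far above 1 expresses the asymmetry that
#' trust is destroyed much faster than it is rebuilt.
#'
#' @param trajectory A single-replication or aggregated trajectory tibble.
#' @param t_enlightenment Time of enlightenment (> 0).
#' @return The rate ratio, or `NA` if the post-enlightenment accrual is
#'   zero or negative (undefined recovery).
#' @export
decline_recovery_ratio <- function(trajectory, t_enlightenment) {
  if (t_enlightenment <= 0) abort("t_enlightenment must be positive")
  trajectory <- single_trajectory(trajectory)
  w <- trajectory$mean_subordinate_to_dominant
  tm <- trajectory$time
  if (max(tm) <= t_enlightenment) {
    abort("trajectory does not extend beyond t_enlightenment")
  }
  i_e <- which.min(abs(tm - t_enlightenment))
  i_end <- length(tm)
  decline <- (w[1] - w[i_e]) / t_enlightenment
  recovery <- (w[i_end] - w[i_e]) / (tm[i_end] - t_enlightenment)
  if (recovery <= 0) return(NA_real_)
  decline / recovery
}

#' Convert model time to an equivalent in years
#'
#' Model time counts dyadic interactions in the whole society. Assuming a
#' fixed number of interactions per day across the population, the
#' conversion is `n_interactions / (interactions_per_day * 365)`. For a
#' 100-agent society in which every individual has one interaction per day
#' (50 interactions per day in total), a 1e7-interaction run spans more
#' than 500 years.
#'
#' @param n_interactions Number of interactions (periods).
#' @param interactions_per_day Population-wide interactions per day (> 0).
#' @return Equivalent duration in years.
#' @examples
#' years_equivalent(1e7, 50)
#' @export
years_equivalent <- function(n_interactions, interactions_per_day = 50) {
  if (any(interactions_per_day <= 0)) {
    abort("interactions_per_day must be positive")
  }
  n_interactions / (interactions_per_day * 365)
}

#' Average trajectories pointwise across replications
#'
#' All replications of a run share one checkpoint grid; the aggregate
#' trajectory is the pointwise mean of every recorded series, the
#' noise-offsetting average the model's summary figures are read from.
#'
#' @param trajectory A trajectory tibble with a `replication` column (as
#'   returned by [tidy()] on a [simulate_society()] result).
#' @return A tibble with one row per checkpoint time and the pointwise
#'   means of all `mean_*` columns.
#' @export
aggregate_replications <- function(trajectory) {
  if (!all(c("time", "mean_dominant_to_subordinate") %in% names(trajectory))) {
    abort("not a trajectory tibble")
  }
  if ("replication" %in% names(trajectory)) {
    grids <- dplyr::summarise(
      dplyr::group_by(trajectory, .data$replication),
      key = paste(sort(.data$time), collapse = ","), .groups = "drop")
    if (length(unique(grids$key)) > 1) {
      abort("replications are on different checkpoint grids")
    }
  }
  out <- dplyr::summarise(
    dplyr::group_by(trajectory, .data$time),
    dplyr::across(dplyr::starts_with("mean_"), mean),
    .groups = "drop")
  dplyr::arrange(out, .data$time)
}
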