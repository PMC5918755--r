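#' Total pairwise belief distance of one group member
#'
#' The total distance of member `i` is the sum of absolute differences
#' between its belief and every group member's belief (the self term
#' contributes zero). Members whose beliefs sit close to their peers'
#' have small total distance and therefore receive large weight in the
#' group norm.
#'
#' This is the direct O(n) summation; the simulation engine maintains the
#' same quantities incrementally through a sorted prefix-sum structure, and
#' the two are checked against each other in the test suite.
#'
#' @param beliefs Numeric vector of the group members' beliefs.
#' @param i Index of the member.
#' @return Non-negative total distance.
#' @examples
#' total_distance(c(0, 0.5, 1), 2) # 1
#' @export
total_distance <- function(beliefs, i) {
  if (length(beliefs) == 0) abort("beliefs must be non-empty")
  if (i < 1 || i > length(beliefs)) abort("member index out of range")
  sum(abs(beliefs[i] - beliefs))
}

#' Distance-weighted group norm
#'
#' The group's norm of collaboration toward a target group is a weighted
#' average of its members' directed beliefs. Under the primary variant the
#' weight of member `i` is the reciprocal of its total pairwise distance
#' `d_i` ([total_distance()]), so normative members (close to their peers)
#' dominate the norm. The robustness variants weight by the reciprocal of
#' the absolute distance from the arithmetic group mean or median.
#'
#' Degenerate cases: if all beliefs are equal the norm is that common value;
#' members with zero distance (but a non-degenerate group) get the floor
#' distance 1e-12 so that perfectly normative members receive the largest
#' finite weight, continuous with the d -> 0 limit.
#'
#' @param beliefs Numeric vector of member beliefs.
#' @param variant `"inverse_pairwise_distance"` (default),
#'   `"distance_from_mean"` or `"distance_from_median"`.
#' @return The norm, a value within the range of `beliefs`.
#' @examples
#' group_norm(c(0, 0.5, 1)) # 0.5 by symmetry
#' @export
group_norm <- function(beliefs, variant = c("inverse_pairwise_distance",
                                            "distance_from_mean",
                                            "distance_from_median")) {
  variant <- match.arg(variant)
  n <- length(beliefs)
  if (n == 0) abort("beliefs must be non-empty")
  if (n == 1 || diff(range(beliefs)) == 0) return(beliefs[1])
  eps <- 1e-12
  if (variant == "inverse_pairwise_distance") {
    d <- vapply(seq_len(n), function(i) total_distance(beliefs, i), numeric(1))
    d <- pmax(d, eps)
  } else {
    m <- if (variant == "distance_from_mean") mean(beliefs) else median(beliefs)
    d <- abs(beliefs - m) + eps
  }
  w <- 1 / d
  sum(beliefs * w) / sum(w)
}

#' Conformity-modulated learning rate
#'
#' Under social conformity an agent's learning speed equals the absolute
#' deviation of its belief from its group's norm: agents near the norm are
#' "sticky" and barely learn from individual experience, agents far from it
#' adjust quickly. Both arguments lie in \[0, 1\], so the result does too.
#'
#' @param belief The agent's directed belief.
#' @param norm The group norm toward the same target group.
#' @return Learning rate in \[0, 1\].
#' @examples
#' learning_rate(0.2, 0.5) # 0.3
#' @export
learning_rate <- function(belief, norm) {
  if (any(belief < 0 | belief > 1) || any(norm < 0 | norm > 1)) {
    abort("belief and norm must lie in [0, 1]")
  }
  abs(belief - norm)
}

#' Audit the incremental norm maintenance against from-scratch recomputation
#'
#' Applies a sequence of single-member belief changes through the engine's
#' incrementally maintained sorted structure and returns the resulting
#' member distances and norm, for comparison with the brute-force
#' [total_distance()] / [group_norm()] path. Used by the test suite; also
#' available inside long runs via the `audit_interval` configuration key.
#'
#' @param beliefs Initial belief vector.
#' @param members Integer vector of member indices changed, in order.
#' @param new_values Numeric vector of the new belief values.
#' @param variant Norm variant, as in [group_norm()].
#' @return A list with `distances` (per-member total distance after all
#'   updates, in member order), `norm`, `norms_after_each` and the
#'   maintained `sorted` belief vector.
#' @export
norm_audit <- function(beliefs, members, new_values,
                       variant = "inverse_pairwise_distance") {
  stopifnot(length(members) == length(new_values))
  cpp_norm_incremental_audit(as.numeric(beliefs), as.integer(members),
                             as.numeric(new_values), variant)
}
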