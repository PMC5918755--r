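---
title: "Modelling intergroup trust dynamics under prejudice and conformity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intergroup trust dynamics under prejudice and conformity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stigmasim)
```

## The model

`stigmasim` simulates a society of two groups — a dominant group $I$ and a
subordinate group $J$ — whose members repeatedly meet in randomly sampled
dyads and play a two-strategy coordination game: both players gain more if
both collaborate than if both defect, there is no incentive to cheat, only
to match the partner. Because intentions cannot be credibly revealed,
players act on *beliefs*. Every agent holds one directed belief per group,
$\rho_{i:G,t} \in [0,1]$, interpreted both as its estimate of how likely a
member of group $G$ is to collaborate and as its own probability of
choosing the collaborative strategy toward that group.

One period of model time is one dyadic interaction (the natural clock for a
process in which only participants change). In each period:

1. A dyad is drawn uniformly from all unordered pairs of distinct agents,
   so cross-group encounters occur in proportion to $|I|\cdot|J|$.
2. Both agents simultaneously choose collaborate (1) or defect (0) from
   their pre-interaction belief toward the partner's group — by default a
   Bernoulli draw with success probability equal to the belief.
3. Each agent then updates that same directed belief by exponential
   smoothing toward the partner's observed action $s$:
   $$\rho_{t} = \alpha\, s + (1-\alpha)\, \rho_{t-1},$$
   a convex combination that keeps beliefs in $[0,1]$ for any
   $\alpha \in [0,1]$.

Prejudice enters only through the initial conditions: subordinate agents'
beliefs toward the dominant group start at $U(0,1)$, while dominant agents'
beliefs toward the subordinate group start at $U(0,\theta)$ with
$\theta < 1$ — an unfairly low estimate of the subordinate group's actual
willingness. A truncated-normal family (rejection-sampled into $(0,1)$) is
available for robustness scenarios.

## Conformity and the group norm

With a constant $\alpha > 0$ the bias washes out — but not before the
subordinate group, rationally responding to discrimination, suppresses its
own willingness; both groups meet near a depressed common level. The
mechanism that makes stigma *persist* is social conformity: the learning
speed of agent $i$ at time $t$ is set to its distance from the group's norm,
$$\alpha_{i,t} = \left|\rho_{i:J,t} - \rho_{I:J,t}\right|,$$
so beliefs are sticky near the norm and malleable away from it. The norm
itself is a distance-weighted average: each member's total distance
$d_{i,t} = \sum_{k \in I} |\rho_{i:J,t} - \rho_{k:J,t}|$ determines a
weight $1/d_{i,t}$, and
$$\rho_{I:J,t} = \frac{\sum_i \rho_{i:J,t}\, d_{i,t}^{-1}}
                      {\sum_i d_{i,t}^{-1}},$$
so normative members dominate the norm. Two robustness variants
(`distance_from_mean`, `distance_from_median`) replace $d_i$ with the
distance from the arithmetic mean or median. The direction of weighting in
these variants is genuinely open — "weight by the distance" could mean
direct or inverse weighting — and we chose inverse weighting for
consistency with the primary formula's logic, where proximity to peers
increases influence.

Degenerate inputs are handled by a continuity rule: if all member beliefs
coincide the norm is that common value; if some (not all) members have
$d_i = 0$, those distances are floored at $\varepsilon = 10^{-12}$, giving
perfectly normative members the largest finite weight — the limit behaviour
of the exact formula as $d_i \to 0$.

Under conformity, group-average $\alpha$ decays as each group consolidates
around its norm. Decisively, decay outruns convergence: cross-group
interactions move the group *average* (and hence everyone's $\alpha$)
while only participants move their own belief, so learning shuts down
before the prejudice gap closes and an alienated subordinate group
coexists indefinitely with a prejudiced dominant group.

## Interventions

Two enlightenment schedules act on the dominant group:

* **Instant enlightenment** (`instant_enlightenment`): from
  $T_e$ onward, every dominant agent is replaced each period by a
  perfectly enlightened individual holding equal beliefs toward both
  groups. We implement the per-period replacement as a per-agent baseline
  drawn once at $T_e$ from $U(0,1)$ and re-imposed every period — an
  enlightened agent whose belief cannot drift is observationally identical
  to a fresh replacement each period, and much cheaper. A literal
  redraw-each-period variant is available (`baseline_mode = "redraw"`).
  The distribution of enlightened beliefs is not pinned down by the
  equality constraint alone; $U(0,1)$ is the neutral choice.
* **Gradual replacement** (`gradual_replacement`): one uniformly chosen
  dominant agent is replaced every `replacement_interval` periods (default
  100) by an enlightened newcomer who, by default, learns normally
  afterwards and is subject to the same conformity — they are new members
  of the society, not permanent saints.

Interventions are applied after the learning step at each interaction
count, a fixed ordering chosen for reproducibility.

## Summary statistics

Trajectories record, at roughly 200 log-spaced checkpoints (always
including $t=0$ and the horizon), each group's mean out-group willingness
and mean learning rate. All summary statistics are pure functions of these
trajectories:

* `convergence_time()` — first recorded time at which the absolute gap
  between the two groups' means falls below a threshold (default
  $10^{-4}$); `NA` when learning is off and the gap never closes. Because
  the gap is only observed on the checkpoint grid the crossing time is
  quantised, about 5% in log time at the default grid density.
* `unrecovered_trust()` — dominant-minus-subordinate mean willingness at
  the checkpoint nearest $T_e + \Delta$ (default $\Delta = 10^7$).
* `decline_recovery_ratio()` — ratio of mean per-period rates
  $[(w(0)-w(T_e))/T_e] \,/\, [(w(\mathrm{end})-w(T_e))/(\mathrm{end}-T_e)]$
  for the subordinate group's willingness $w$; "average rate" is taken as
  the endpoint difference over the elapsed span, not a regression slope —
  the windowing behind the reference value is not fully specified, and the
  endpoint definition is the least arbitrary choice. `NA` when the
  post-enlightenment accrual is zero or negative.
* `years_equivalent()` — divides interactions by a population-wide daily
  interaction rate; at 50 interactions per day a $10^7$-interaction run
  spans over 500 years, which is why these are cross-generational
  dynamics.

## Performance and numerical choices

A $10^7$-interaction run cannot recompute $O(n^2)$ pairwise distances each
period, so the compiled engine maintains, per (observer group, target
group) pair, a sorted vector of member beliefs. A full norm evaluation is
then a single $O(n)$ prefix-sum pass, and a belief change is one sorted
splice. The running total of beliefs is refreshed periodically to stop
floating-point drift. The identical quantities are implemented in plain R
(`total_distance()`, `group_norm()`) by direct summation; the test suite
replays complete engine traces through the R path step by step and audits
the incremental structures against from-scratch recomputation (also
available inside any run via `audit_interval`).

Randomness flows from one master seed through named PCG32 substreams —
initialization (cross-group and in-group separately), dyad sampling, each
group's action draws, and interventions — with per-replication derivation.
Besides reproducibility this buys a strong structural guarantee, which the
tests assert bit-for-bit: changing the in-group prior changes nothing in
the cross-group trajectories, because in-group and cross-group dynamics
never mix. Both dyad members act from pre-interaction beliefs and both
then update, with conformity rates evaluated on the pre-interaction belief
configuration, removing any within-interaction order dependence. One
uniform is consumed per participant regardless of the action rule so that
the Bernoulli and threshold variants run on the same random sequence.

Open modelling choices we fixed, and why:

* **Actions are Bernoulli draws** in the belief, since the belief is
  defined as a *probability* of collaborating; a deterministic threshold
  rule (collaborate iff belief $\ge 0.5$) is offered as a variant.
* **In-group beliefs are simulated** (default prior $U(0,1)$ for both
  groups) even though they do not feed back on cross-group results — the
  decoupling property makes cross-group dynamics provably insensitive to
  this choice, and modelling them keeps within-group encounters
  meaningful under one uniform mechanism: conformity applies to whichever
  directed belief is being updated, using the observer group's norm
  toward the target group.
* **A horizon of 0 is legal** and returns the initial state, which gives
  the natural base case for trajectory consumers.

## What the simulations do and do not show

The simulator is the study's data generator: its defaults are the studied
conditions ($|I| = 80$, $|J| = 20$, $\theta = 0.5$, conformity learning,
$10^7$ interactions), and the preset registry pins every published
variation (prejudice magnitude, population size 1000, inverted group
sizes, collaborative/distrustful populations, truncated-normal priors,
enlightenment schedules). Real societies are not well-mixed dyadic
populations: there is no network or spatial structure, no memory of
individual partners (beliefs are group-directed), no payoff or wealth
accounting, and the groups differ only in size and initial beliefs.
Passing tests therefore demonstrate properties of this mechanism — that
prejudiced priors plus conformity suffice to lock in intergroup mistrust —
not calibrated predictions for any actual society.

Test and acceptance runs use deliberately chosen problem sizes: the
conformity headline runs keep the full $10^7$-interaction horizon but use
10 replications rather than 100; qualitative robustness scenarios run to
$10^6$ interactions with 2 replications; the enlightenment-delay sweep
uses 5 replications; the constant-$\alpha$ convergence level uses 100
replications (individual runs absorb at all-collaborate or all-defect, so
the common level is only identified by a large replication average — and
constant-$\alpha$ runs cost almost nothing); and the decline/recovery
ratio uses 20 replications because its denominator, the aggregate
post-enlightenment accrual, is small and heavy-tailed across runs. These
sizes keep the full suite reproducible on a single core in minutes while
leaving Monte-Carlo standard errors inside the tolerances being asserted.

## Known limitations

* The decline/recovery rate ratio is sensitive to the averaging window
  and to the (unspecified) distribution of enlightened baselines; we
  reproduce its order of magnitude and the qualitative asymmetry, not its
  exact value.
* Convergence times are read off the checkpoint grid, not exact crossing
  times.
* The incremental norm structure assumes beliefs are finite doubles in
  $[0,1]$; the configuration validator enforces this at the boundary.
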