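test_that("the engine's conformity dynamics replay exactly through the reference path", {
  cfg <- model_config(n_dominant = 30, n_subordinate = 10, horizon = 400,
                      checkpoints = 20)
  expect_lt(replay_max_deviation(cfg, seed = 101), 1e-9)
})

test_that("the engine's constant-alpha dynamics replay exactly through the reference path", {
  cfg <- model_config(n_dominant = 30, n_subordinate = 10, horizon = 300,
                      alpha_mode = "constant", checkpoints = 20)
  expect_lt(replay_max_deviation(cfg, seed = 55), 1e-9)
})

test_that("norm variants replay exactly too", {
  for (variant in c("distance_from_mean", "distance_from_median")) {
    cfg <- model_config(n_dominant = 15, n_subordinate = 5, horizon = 200,
                        norm_variant = variant, checkpoints = 20)
    expect_lt(replay_max_deviation(cfg, seed = 77), 1e-9)
  }
})

test_that("one interaction changes at most the two participants' beliefs", {
  cfg <- small_config(horizon = 1)
  for (seed in 1:20) {
    sim <- simulate_society(cfg, seed = seed, replications = 1, trace = TRUE)
    init <- sim$initial_states[[1]]
    final <- sim$final_states[[1]]
    a <- sim$traces[[1]]$agent_a
    b <- sim$traces[[1]]$agent_b
    changed <- which(init$belief_toward_dominant != final$belief_toward_dominant |
                     init$belief_toward_subordinate != final$belief_toward_subordinate)
    expect_lte(length(changed), 2)
    expect_true(all(changed %in% c(a, b)))
    # non-participants are bit-identical
    others <- setdiff(init$agent, c(a, b))
    expect_identical(init[others, ], final[others, ])
  }
})

test_that("a within-group dyad only touches in-group beliefs", {
  cfg <- small_config(horizon = 1)
  found <- FALSE
  for (seed in 1:40) {
    sim <- simulate_society(cfg, seed = seed, replications = 1, trace = TRUE)
    tr <- sim$traces[[1]]
    init <- sim$initial_states[[1]]
    final <- sim$final_states[[1]]
    ga <- init$group[tr$agent_a]
    gb <- init$group[tr$agent_b]
    if (ga == "dominant" && gb == "dominant") {
      found <- TRUE
      # beliefs toward the subordinate group are untouched everywhere
      expect_identical(init$belief_toward_subordinate,
                       final$belief_toward_subordinate)
    }
  }
  expect_true(found)
})

test_that("updates move beliefs toward the observed action", {
  cfg <- model_config(alpha_mode = "constant", alpha_constant = 0.25,
                      horizon = 0)
  pop <- init_population(cfg, seed = 3)
  i <- which(pop$group == "dominant")[1]
  j <- which(pop$group == "subordinate")[1]
  rho_i <- pop$belief_toward_subordinate[i]
  rho_j <- pop$belief_toward_dominant[j]
  # i collaborates, j defects
  out <- step_interaction(pop, cfg, dyad = c(i, j), actions = c(1, 0))
  expect_equal(out$belief_toward_subordinate[i], 0.75 * rho_i)
  expect_equal(out$belief_toward_dominant[j], 0.25 + 0.75 * rho_j)
  expect_equal(attr(out, "interaction_count"), 1)
})

test_that("the reference step changes exactly the two participants' directed beliefs", {
  cfg <- small_config()
  pop <- init_population(cfg, seed = 9)
  set.seed(1)
  for (k in 1:25) {
    new_pop <- step_interaction(pop, cfg)
    n_changed <- sum(pop$belief_toward_dominant != new_pop$belief_toward_dominant) +
      sum(pop$belief_toward_subordinate != new_pop$belief_toward_subordinate)
    expect_lte(n_changed, 2)
    pop <- new_pop
  }
  expect_true(all(pop$belief_toward_dominant >= 0 &
                    pop$belief_toward_dominant <= 1 &
                    pop$belief_toward_subordinate >= 0 &
                    pop$belief_toward_subordinate <= 1))
})
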