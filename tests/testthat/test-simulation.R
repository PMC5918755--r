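test_that("identical configuration and seed reproduce bit-identical runs", {
  cfg <- small_config(horizon = 3000)
  s1 <- simulate_society(cfg, seed = 42, replications = 2)
  s2 <- simulate_society(cfg, seed = 42, replications = 2)
  expect_identical(s1$trajectories, s2$trajectories)
  expect_identical(s1$final_states, s2$final_states)
  s3 <- simulate_society(cfg, seed = 43, replications = 2)
  expect_false(identical(s1$trajectories, s3$trajectories))
})

test_that("a zero-horizon run records only the initial state", {
  cfg <- small_config(horizon = 0)
  sim <- simulate_society(cfg, seed = 2, replications = 1)
  expect_equal(nrow(sim$trajectories), 1)
  expect_equal(sim$trajectories$time, 0)
  expect_identical(sim$initial_states[[1]], sim$final_states[[1]])
  init <- sim$initial_states[[1]]
  expect_equal(sim$trajectories$mean_dominant_to_subordinate,
               mean_willingness(init, "dominant", "subordinate"))
})

test_that("with no learning the initial prejudices persist exactly", {
  cfg <- model_config(alpha_mode = "constant", alpha_constant = 0,
                      horizon = 1e4, checkpoints = 40)
  sim <- simulate_society(cfg, seed = 17, replications = 1)
  expect_identical(sim$initial_states[[1]], sim$final_states[[1]])
  tr <- sim$trajectories
  expect_true(all(tr$mean_dominant_to_subordinate ==
                    tr$mean_dominant_to_subordinate[1]))
  # the two groups never converge: sentinel convergence time
  expect_true(is.na(convergence_time(tr)))
})

test_that("in-group initialization cannot perturb cross-group dynamics", {
  cfg1 <- model_config(horizon = 2e4, checkpoints = 40)
  cfg2 <- model_config(horizon = 2e4, checkpoints = 40,
                       prior_dominant_in = c(0.2, 0.8),
                       prior_subordinate_in = c(0.4, 0.6))
  s1 <- simulate_society(cfg1, seed = 9, replications = 2)
  s2 <- simulate_society(cfg2, seed = 9, replications = 2)
  expect_identical(s1$trajectories$mean_dominant_to_subordinate,
                   s2$trajectories$mean_dominant_to_subordinate)
  expect_identical(s1$trajectories$mean_subordinate_to_dominant,
                   s2$trajectories$mean_subordinate_to_dominant)
  for (r in 1:2) {
    expect_identical(
      s1$final_states[[r]]$belief_toward_subordinate[
        s1$final_states[[r]]$group == "dominant"],
      s2$final_states[[r]]$belief_toward_subordinate[
        s2$final_states[[r]]$group == "dominant"])
  }
  # but the in-group beliefs themselves did change
  expect_false(identical(s1$final_states[[1]]$belief_toward_dominant,
                         s2$final_states[[1]]$belief_toward_dominant))
})

test_that("the periodic norm-state audit passes on a conformity run", {
  cfg <- model_config(horizon = 2e4, checkpoints = 20, audit_interval = 1000)
  expect_no_error(simulate_society(cfg, seed = 4, replications = 1))
})

test_that("tidy, glance and the plot functions expose the run coherently", {
  sim <- simulate_society(small_config(horizon = 2000), seed = 10,
                          replications = 3)
  tr <- tidy(sim)
  expect_s3_class(tr, "tbl_df")
  expect_equal(sort(unique(tr$replication)), 1:3)
  expect_true(all(tr$mean_dominant_to_subordinate >= 0 &
                    tr$mean_dominant_to_subordinate <= 1))
  g <- glance(sim)
  expect_equal(nrow(g), 1)
  expect_equal(g$replications, 3)
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(plot_trajectory(aggregate_replications(tr)), "ggplot")
  expect_s3_class(plot_learning_rates(tr), "ggplot")
  expect_output(print(sim), "trust_sim")
})

test_that("summaries of an enlightenment run include the recovery statistics", {
  cfg <- model_config(intervention_mode = "instant_enlightenment",
                      t_enlightenment = 500, horizon = 5000, checkpoints = 40)
  sim <- simulate_society(cfg, seed = 5, replications = 2)
  expect_true(all(is.finite(sim$summaries$unrecovered_trust)))
  g <- glance(sim)
  expect_true(is.finite(g$mean_unrecovered_trust))
})
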