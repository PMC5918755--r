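test_that("enlightened dominant agents treat both groups identically", {
  pop <- init_population(model_config(horizon = 0), seed = 21)
  set.seed(4)
  out <- apply_instant_enlightenment(pop)
  dom <- out$group == "dominant"
  expect_equal(max(abs(out$belief_toward_dominant[dom] -
                         out$belief_toward_subordinate[dom])), 0)
  # subordinate agents are bit-identical
  expect_identical(pop[!dom, ], out[!dom, ])
  # re-applying with the same baselines is a no-op
  baselines <- out$belief_toward_dominant[dom]
  expect_identical(apply_instant_enlightenment(out, baselines), out)
  expect_identical(dplyr::count(out, group), dplyr::count(pop, group))
})

test_that("gradual replacement renews one dominant agent with equal beliefs", {
  pop <- init_population(model_config(horizon = 0), seed = 22)
  set.seed(5)
  out <- apply_gradual_replacement(pop)
  changed <- which(pop$belief_toward_dominant != out$belief_toward_dominant |
                   pop$belief_toward_subordinate != out$belief_toward_subordinate)
  expect_length(changed, 1)
  expect_equal(out$group[changed], factor("dominant",
               levels = c("dominant", "subordinate")))
  expect_equal(out$belief_toward_dominant[changed],
               out$belief_toward_subordinate[changed])
  expect_error(apply_gradual_replacement(pop, member = nrow(pop)),
               "dominant")
})

test_that("the engine applies exactly one replacement per interval", {
  cfg <- model_config(intervention_mode = "gradual_replacement",
                      t_enlightenment = 0, replacement_interval = 100,
                      horizon = 1e4, checkpoints = 30)
  sim <- simulate_society(cfg, seed = 6, replications = 1)
  ev <- sim$replacement_events
  expect_equal(nrow(ev), 100)
  expect_equal(ev$time, seq(100, 1e4, by = 100))
  expect_true(all(ev$agent >= 1 & ev$agent <= cfg$n_dominant))
})

test_that("no intervention means no replacement events and unchanged schedule", {
  sim <- simulate_society(small_config(), seed = 1, replications = 1)
  expect_equal(nrow(sim$replacement_events), 0)
})

test_that("instant enlightenment holds dominant beliefs equal and frozen", {
  base <- list(intervention_mode = "instant_enlightenment",
               t_enlightenment = 100, checkpoints = 30)
  cfg_short <- do.call(model_config, c(base, list(horizon = 2000)))
  cfg_long <- do.call(model_config, c(base, list(horizon = 5000)))
  s1 <- simulate_society(cfg_short, seed = 14, replications = 1)
  s2 <- simulate_society(cfg_long, seed = 14, replications = 1)
  f1 <- s1$final_states[[1]]
  f2 <- s2$final_states[[1]]
  dom <- f1$group == "dominant"
  # equal beliefs toward both groups, at both horizons
  expect_equal(f1$belief_toward_dominant[dom],
               f1$belief_toward_subordinate[dom])
  # frozen baselines: identical at t = 2000 and t = 5000
  expect_identical(f1[dom, ], f2[dom, ])
  # the subordinate group, meanwhile, keeps learning
  expect_false(identical(f1[!dom, ], f2[!dom, ]))
})

test_that("redraw mode keeps the equality constraint with fresh generations", {
  cfg <- model_config(intervention_mode = "instant_enlightenment",
                      t_enlightenment = 50, baseline_mode = "redraw",
                      horizon = 300, checkpoints = 20)
  s1 <- simulate_society(cfg, seed = 3, replications = 1)
  f1 <- s1$final_states[[1]]
  dom <- f1$group == "dominant"
  expect_equal(f1$belief_toward_dominant[dom],
               f1$belief_toward_subordinate[dom])
})

test_that("after enlightenment the dominant group's two mean willingness values coincide", {
  cfg <- model_config(intervention_mode = "instant_enlightenment",
                      t_enlightenment = 100, horizon = 1000, checkpoints = 25)
  sim <- simulate_society(cfg, seed = 8, replications = 1)
  f <- sim$final_states[[1]]
  expect_equal(mean_willingness(f, "dominant", "subordinate"),
               mean_willingness(f, "dominant", "dominant"))
})
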