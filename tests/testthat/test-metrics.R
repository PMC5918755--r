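toy_trajectory <- function(times, dom, sub) {
  tibble::tibble(time = times,
                 mean_dominant_to_subordinate = dom,
                 mean_subordinate_to_dominant = sub,
                 mean_alpha_dominant = 0.1,
                 mean_alpha_subordinate = 0.1)
}

test_that("mean willingness is the arithmetic group mean of directed beliefs", {
  pop <- tibble::tibble(
    agent = 1:4,
    group = factor(c("dominant", "dominant", "subordinate", "subordinate"),
                   levels = c("dominant", "subordinate")),
    belief_toward_dominant = c(0.9, 0.7, 0.2, 0.6),
    belief_toward_subordinate = c(0.4, 0.4, 0.5, 0.1))
  expect_equal(mean_willingness(pop, "dominant", "subordinate"), 0.4)
  expect_equal(mean_willingness(pop, "subordinate", "dominant"), 0.4)
  expect_equal(mean_willingness(pop, "dominant", "dominant"), 0.8)
  empty <- pop[pop$group == "dominant", ]
  expect_error(mean_willingness(empty, "subordinate", "dominant"), "no agents")
})

test_that("convergence time is the first gap crossing on the grid", {
  tr <- toy_trajectory(c(0, 10, 100, 1000),
                       dom = c(0.25, 0.30, 0.31, 0.31002),
                       sub = c(0.50, 0.31, 0.31005, 0.31001))
  expect_equal(convergence_time(tr, threshold = 1e-4), 100)
  expect_equal(convergence_time(toy_trajectory(c(0, 5), c(0.4, 0.4),
                                               c(0.4, 0.4))), 0)
  # never converges -> sentinel
  expect_true(is.na(convergence_time(toy_trajectory(c(0, 10), c(0.2, 0.2),
                                                    c(0.5, 0.5)))))
  expect_error(convergence_time(tr, threshold = 0), "positive")
})

test_that("convergence time is monotone non-increasing in the threshold", {
  set.seed(20)
  gaps <- sort(runif(30, 0, 0.3), decreasing = TRUE)
  tr <- toy_trajectory(seq(0, 290, by = 10), dom = 0.3 + gaps, sub = rep(0.3, 30))
  thresholds <- c(0.001, 0.01, 0.05, 0.1, 0.2, 0.4)
  ct <- vapply(thresholds, function(th) {
    v <- convergence_time(tr, th)
    if (is.na(v)) Inf else v
  }, numeric(1))
  expect_true(all(diff(ct) <= 0))
})

test_that("unrecovered trust is the group gap at the evaluation checkpoint", {
  tr <- toy_trajectory(c(0, 1e4, 5e6, 1.001e7),
                       dom = c(0.25, 0.5, 0.6, 0.7),
                       sub = c(0.50, 0.44, 0.42, 0.40))
  expect_equal(unrecovered_trust(tr, 1e4, delta = 1e7), 0.3)
  expect_equal(unrecovered_trust(toy_trajectory(c(0, 2e7), c(0.4, 0.5),
                                                c(0.5, 0.5)), 1e4), 0)
  expect_error(unrecovered_trust(tr, 1e6, delta = 1e7), "ends at")
})

test_that("the decline/recovery ratio follows its defining arithmetic", {
  # decline 0.2 over 1e4, recovery 0.1 over 1e7 -> 2000
  tr <- toy_trajectory(c(0, 1e4, 1e4 + 1e7),
                       dom = c(0.3, 0.3, 0.3),
                       sub = c(0.5, 0.3, 0.4))
  expect_equal(decline_recovery_ratio(tr, 1e4), 2000)
  # symmetric decline and recovery over equal spans -> 1
  sym <- toy_trajectory(c(0, 100, 200), dom = rep(0.3, 3),
                        sub = c(0.5, 0.4, 0.5))
  expect_equal(decline_recovery_ratio(sym, 100), 1)
  # flat recovery -> undefined sentinel
  flat <- toy_trajectory(c(0, 100, 200), dom = rep(0.3, 3),
                         sub = c(0.5, 0.4, 0.4))
  expect_true(is.na(decline_recovery_ratio(flat, 100)))
  expect_error(decline_recovery_ratio(sym, 0), "positive")
})

test_that("model time converts to years by population interaction rate", {
  expect_equal(years_equivalent(1e7, 50), 1e7 / (50 * 365))
  expect_gt(years_equivalent(1e7, 50), 500)
  for (r in c(0.5, 3, 50)) expect_equal(years_equivalent(365 * r, r), 1)
  expect_equal(years_equivalent(1e7, 100), years_equivalent(1e7, 50) / 2)
  expect_error(years_equivalent(10, 0), "positive")
})

test_that("replication aggregation is a pointwise mean", {
  t1 <- toy_trajectory(c(0, 10), c(0.2, 0.2), c(0.6, 0.6))
  t2 <- toy_trajectory(c(0, 10), c(0.4, 0.4), c(0.4, 0.4))
  both <- dplyr::bind_rows(dplyr::mutate(t1, replication = 1L),
                           dplyr::mutate(t2, replication = 2L))
  agg <- aggregate_replications(both)
  expect_equal(agg$mean_dominant_to_subordinate, c(0.3, 0.3))
  expect_equal(agg$mean_subordinate_to_dominant, c(0.5, 0.5))
  # single replication: aggregate equals that replication
  one <- dplyr::mutate(t1, replication = 1L)
  expect_equal(aggregate_replications(one)$mean_dominant_to_subordinate,
               t1$mean_dominant_to_subordinate)
  # permutation invariance
  shuffled <- both[sample(nrow(both)), ]
  expect_equal(aggregate_replications(shuffled), agg)
  # mismatched grids are an error
  bad <- dplyr::bind_rows(dplyr::mutate(t1, replication = 1L),
                          dplyr::mutate(toy_trajectory(c(0, 20), c(0.1, 0.1),
                                                       c(0.2, 0.2)),
                                        replication = 2L))
  expect_error(aggregate_replications(bad), "grids")
  # multi-replication input must be aggregated before scalar metrics
  expect_error(convergence_time(both), "aggregate")
})

test_that("summary statistics survive a CSV round trip exactly", {
  sim <- simulate_society(small_config(horizon = 2000), seed = 12,
                          replications = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tidy(sim), path, config = sim$config)
  back <- read_trajectory(path)
  agg0 <- aggregate_replications(tidy(sim))
  agg1 <- aggregate_replications(back)
  expect_equal(agg1, agg0, tolerance = 1e-12)
  expect_equal(convergence_time(agg1), convergence_time(agg0))
})
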